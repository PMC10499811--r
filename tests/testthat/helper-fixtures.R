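# Shared fixtures, built in code.

# A tiny 3-sample x 2-assay matrix with known values.
tiny_npx <- function() {
  v <- matrix(c(1.5, 2.5, 3.5,
                4.0, 5.0, 6.0), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("DDC_panelA", "CRH_panelB")))
  npx_matrix(v, lod = c(DDC_panelA = 0.5, CRH_panelB = 1),
             batch = c("R1", "R1", "R2"),
             panel = c(DDC_panelA = "panelA", CRH_panelB = "panelB"))
}

# Small three-group design for fast end-to-end runs; strong planted effects.
small_design <- function(n_proteins = 60,
                         group_sizes = c(CON = 60, DLB = 40, AD = 70),
                         ...) {
  effect_spec <- data.frame(
    class = c("shared_divergent", "ad_specific", "general_dementia",
              "dlb_unique", "null"),
    count = c(3, 2, 10, 5, n_proteins - 20),
    beta_dlb_vs_con = c(0.9, 0, 0.35, -0.8, 0),
    beta_ad_vs_con = c(-0.4, 0.8, 0.35, 0, 0),
    tag = c("panel", "panel", "", "", ""),
    stringsAsFactors = FALSE)
  cohort_design(
    group_sizes = group_sizes,
    age_dist = list(CON = c(58, 8), DLB = c(69, 8), AD = c(66, 8)),
    male_frac = c(CON = 0.6, DLB = 0.8, AD = 0.6),
    n_proteins = n_proteins, effect_spec = effect_spec, ...)
}

# Metadata + diagnosis-contrast extraction used by several tests.
contrast_xy <- function(sim, group_a, group_b, assays = NULL) {
  meta <- sim$metadata
  keep <- !meta$is_bridge & meta$diagnosis %in% c(group_a, group_b)
  ids <- meta$sample_id[keep]
  sub <- meta[match(ids, meta$sample_id), ]
  X <- sim$npx$values[ids, assays %||% colnames(sim$npx$values), drop = FALSE]
  list(X = X, y = as.numeric(sub$diagnosis == group_b),
       covs = cbind(age = sub$age - mean(sub$age),
                    sex = as.numeric(sub$sex == "M")),
       meta = sub)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
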