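#' Specify a synthetic CSF proteomics cohort
#'
#' A cohort design states everything the generator needs: group sizes and
#' demographics for the three diagnosis groups (CON, DLB, AD), the number of
#' protein assays, the planted per-class effect sizes, confounder strength,
#' LOD censoring level, and the batch/bridging layout. Effects are expressed
#' as shifts (log2 NPX units) of DLB and AD relative to controls, so
#' `beta_dlb_vs_con` is the true log2 fold-change of the DLB-vs-CON
#' contrast.
#'
#' Effect classes follow the UpSet vocabulary of the analysis:
#' `dlb_unique` (differs from both CON and AD, not AD vs CON),
#' `general_dementia` (same shift in both dementias), `shared_divergent`
#' (changed in both contrasts with distinct dementia levels), `ad_specific`
#' (AD shifted, DLB not) and `null`.
#'
#' @param group_sizes named integer vector `c(CON=, DLB=, AD=)`.
#' @param age_dist named list per group of `c(mean, sd)` in years.
#' @param male_frac named numeric vector per group, proportions in `[0,1]`.
#' @param n_proteins number of assays to simulate.
#' @param effect_spec data.frame with columns `class`, `count`,
#'   `beta_dlb_vs_con`, `beta_ad_vs_con` and optional `tag` (e.g. `"panel"`
#'   to designate planted signature markers); counts must sum to
#'   `n_proteins`.
#' @param within_group_sd residual SD of NPX within a diagnosis group (log2
#'   units).
#' @param age_slope,age_slope_frac slope (log2 units per year of age, applied
#'   to centered age) and the fraction of proteins that carry it.
#' @param sex_shift,sex_shift_frac additive shift for male sex and the
#'   fraction of proteins that carry it.
#' @param lod_quantile per-assay censoring level: a scalar quantile or a
#'   range `c(lo, hi)` from which each assay's quantile is drawn uniformly.
#' @param n_batches,batch_sd number of measurement rounds and the SD of the
#'   per-(batch, assay) offsets applied to non-reference batches.
#' @param n_bridges number of bridging samples re-measured in every batch.
#' @param bridge_noise_sd technical noise SD added independently to each
#'   re-measurement of a bridging sample (0 = pure aliquots).
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes,
                          age_dist,
                          male_frac,
                          n_proteins,
                          effect_spec,
                          within_group_sd = 0.5,
                          age_slope = 0.02,
                          age_slope_frac = 0.2,
                          sex_shift = 0.15,
                          sex_shift_frac = 0.2,
                          lod_quantile = c(0.02, 0.15),
                          n_batches = 2,
                          batch_sd = 0.2,
                          n_bridges = 16,
                          bridge_noise_sd = 0) {
  groups <- c("CON", "DLB", "AD")
  if (!all(groups %in% names(group_sizes)))
    stopf("group_sizes must name CON, DLB and AD")
  if (any(group_sizes <= 0)) stopf("group sizes must be positive")
  if (any(male_frac < 0 | male_frac > 1)) stopf("male_frac must be in [0,1]")
  if (within_group_sd <= 0) stopf("within_group_sd must be positive")
  if (any(vapply(age_dist, function(g) g[2] <= 0, logical(1))))
    stopf("age SDs must be positive")
  req <- c("class", "count", "beta_dlb_vs_con", "beta_ad_vs_con")
  if (!all(req %in% names(effect_spec)))
    stopf("effect_spec needs columns %s", paste(req, collapse = ", "))
  known <- c("dlb_unique", "general_dementia", "shared_divergent",
             "ad_specific", "null")
  if (!all(effect_spec$class %in% known))
    stopf("unknown effect class(es): %s",
          paste(setdiff(effect_spec$class, known), collapse = ", "))
  if (sum(effect_spec$count) != n_proteins)
    stopf("effect_spec counts sum to %d but n_proteins is %d",
          sum(effect_spec$count), n_proteins)
  if (any(effect_spec$count < 0)) stopf("effect counts must be >= 0")
  if (any(effect_spec$class == "null" &
          (effect_spec$beta_dlb_vs_con != 0 | effect_spec$beta_ad_vs_con != 0)))
    stopf("null class must have all betas equal to 0")
  if (length(lod_quantile) == 1) lod_quantile <- rep(lod_quantile, 2)
  if (any(lod_quantile < 0 | lod_quantile > 1))
    stopf("lod_quantile must be in [0,1]")
  if (!"tag" %in% names(effect_spec)) effect_spec$tag <- ""
  structure(list(
    group_sizes = group_sizes[groups], age_dist = age_dist[groups],
    male_frac = male_frac[groups], n_proteins = as.integer(n_proteins),
    effect_spec = effect_spec, within_group_sd = within_group_sd,
    age_slope = age_slope, age_slope_frac = age_slope_frac,
    sex_shift = sex_shift, sex_shift_frac = sex_shift_frac,
    lod_quantile = lod_quantile, n_batches = as.integer(n_batches),
    batch_sd = batch_sd, n_bridges = as.integer(n_bridges),
    bridge_noise_sd = bridge_noise_sd), class = "cohort_design")
}

#' Default discovery-cohort design
#'
#' The design the package treats as its reference world: 190 controls, 109
#' DLB and 235 AD samples (534 in total) with the discovery cohort's age and
#' sex distributions, 665 assays, and planted effect classes sized
#' 49 / 17 / 24 (DLB-unique / general-dementia / shared-divergent) plus an
#' AD-specific class and nulls. One DLB-unique marker (a DDC-like dopamine
#' pathway surrogate) is fixed at a DLB-vs-CON effect of 0.95 log2 units.
#' Background effect magnitudes are 0.3 log2 units, chosen so that planted
#' effects are reliably detectable at these sample sizes without being
#' trivially separable; the within-group SD of 0.5 log2 units is a
#' calibration choice, not an observed value.
#'
#' @return a [cohort_design].
#' @export
default_paper_design <- function() {
  effect_spec <- data.frame(
    class = c("dlb_unique", "dlb_unique", "dlb_unique",
              "general_dementia", "general_dementia",
              "shared_divergent", "shared_divergent", "shared_divergent",
              "ad_specific", "ad_specific", "null"),
    count = c(1L, 14L, 34L, 5L, 12L, 15L, 3L, 6L, 10L, 15L, 550L),
    beta_dlb_vs_con = c(0.95, 0.3, -0.3, 0.3, -0.3, -0.3, 0.5, 0.2, 0, 0, 0),
    beta_ad_vs_con = c(0, 0, 0, 0.3, -0.3, 0.3, 0.2, 0.5, 0.4, -0.4, 0),
    tag = c("ddc_like", rep("", 10)),
    stringsAsFactors = FALSE
  )
  cohort_design(
    group_sizes = c(CON = 190L, DLB = 109L, AD = 235L),
    age_dist = list(CON = c(58, 8), DLB = c(69, 8), AD = c(66, 8)),
    male_frac = c(CON = 0.63, DLB = 0.83, AD = 0.59),
    n_proteins = 665L,
    effect_spec = effect_spec
  )
}

#' Planted-panel design for signature-recovery experiments
#'
#' A variant of [default_paper_design()] in which exactly seven designated
#' markers carry the between-dementia (DLB vs AD) information: four
#' DLB-related shared-divergent markers and three AD-specific markers, with
#' DLB-vs-AD separations of 0.8-0.9 log2 units. All other non-null proteins
#' follow the general-dementia pattern (equal shift in both dementias), so
#' they are informative for dementia vs control but carry no DLB-vs-AD
#' signal. This is the world in which exact recovery of the planted
#' signature by the panel-selection pipeline is the correct answer; with the
#' full class structure of [default_paper_design()], background proteins are
#' genuinely (weakly) informative for DLB vs AD and exact set recovery is
#' ill-posed.
#'
#' @return a [cohort_design] whose truth table flags the planted markers
#'   with `tag == "panel"`.
#' @export
default_panel_design <- function() {
  effect_spec <- data.frame(
    class = c(rep("shared_divergent", 4), rep("ad_specific", 3),
              "general_dementia", "general_dementia", "null"),
    count = c(rep(1L, 7), 40L, 43L, 575L),
    beta_dlb_vs_con = c(0.95, -0.55, -0.60, -0.45, 0, 0, 0, 0.3, -0.3, 0),
    beta_ad_vs_con = c(0.15, 0.35, 0.25, 0.40, 0.85, 0.90, 0.80, 0.3, -0.3, 0),
    tag = c(rep("panel", 7), "", "", ""),
    stringsAsFactors = FALSE
  )
  d <- default_paper_design()
  cohort_design(
    group_sizes = d$group_sizes, age_dist = d$age_dist,
    male_frac = d$male_frac, n_proteins = 665L, effect_spec = effect_spec
  )
}

#' Generate a synthetic PEA cohort with ground truth
#'
#' Simulates, for each sample i and protein j,
#' `NPX_ij = mu_j + beta_j[g(i)] + a_j (age_i - mean age) + s_j 1[male]
#' + batch offset + eps`, with `eps ~ Normal(0, within_group_sd)`. Ages are
#' Gaussian per group, sex Bernoulli per group, and each assay's LOD is
#' placed at a stated quantile of its marginal distribution (values below
#' the LOD are retained unless `mask_below_lod = TRUE`). Bridging samples
#' are re-measured in every batch under linked row identifiers.
#'
#' @param design a [cohort_design].
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @param mask_below_lod if `TRUE`, values below the assay LOD are set to
#'   `NA` (to exercise missing-data code paths); default keeps raw values.
#' @return a list with components `npx` (an [npx_matrix] including bridge
#'   rows), `metadata` (data.frame; bridge rows flagged by `is_bridge`),
#'   `truth` (data.frame: `assay_id`, `class`, `beta_dlb_vs_con`,
#'   `beta_ad_vs_con`, `age_slope`, `sex_shift`, `is_panel`) and `bridges`
#'   (data.frame `sample_id`, `bridge_id`, `batch`).
#' @export
generate_cohort <- function(design, seed, mask_below_lod = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  if (missing(seed)) stopf("an explicit seed is required")
  set.seed(seed)
  groups <- names(design$group_sizes)
  n <- sum(design$group_sizes)
  p <- design$n_proteins

  diagnosis <- rep(groups, design$group_sizes)
  ids <- sprintf("S%04d", seq_len(n))
  age <- unlist(lapply(groups, function(g)
    stats::rnorm(design$group_sizes[[g]], design$age_dist[[g]][1],
                 design$age_dist[[g]][2])))
  sex <- unlist(lapply(groups, function(g)
    ifelse(stats::rbinom(design$group_sizes[[g]], 1,
                         design$male_frac[[g]]) == 1, "M", "F")))

  # protein-level truth
  es <- design$effect_spec
  class <- rep(es$class, es$count)
  beta_dlb <- rep(es$beta_dlb_vs_con, es$count)
  beta_ad <- rep(es$beta_ad_vs_con, es$count)
  tag <- rep(es$tag, es$count)
  panel_names <- sprintf("Panel%02d", (seq_len(p) - 1L) %/% 92L + 1L)
  assays <- sprintf("PROT%04d_%s", seq_len(p), panel_names)
  a_slope <- ifelse(stats::runif(p) < design$age_slope_frac, design$age_slope, 0)
  s_shift <- ifelse(stats::runif(p) < design$sex_shift_frac, design$sex_shift, 0)
  mu <- stats::rnorm(p, 5, 1.5)

  beta_by_group <- rbind(CON = rep(0, p), DLB = beta_dlb, AD = beta_ad)
  group_beta <- beta_by_group[diagnosis, , drop = FALSE]

  batches <- sprintf("R%d", seq_len(design$n_batches))
  batch <- sample(rep(batches, length.out = n))
  batch_offset <- matrix(0, design$n_batches, p,
                         dimnames = list(batches, NULL))
  if (design$n_batches > 1)
    batch_offset[-1, ] <- stats::rnorm((design$n_batches - 1) * p,
                                       0, design$batch_sd)

  age_c <- age - mean(age)
  male <- as.numeric(sex == "M")
  signal <- matrix(mu, n, p, byrow = TRUE) + group_beta +
    outer(age_c, a_slope) + outer(male, s_shift)
  eps <- matrix(stats::rnorm(n * p, 0, design$within_group_sd), n, p)
  values <- signal + eps + batch_offset[batch, , drop = FALSE]
  dimnames(values) <- list(ids, assays)

  # bridging samples: one biological draw, re-measured in every batch
  nb <- design$n_bridges
  bridge_rows <- NULL
  bridges <- data.frame(sample_id = character(), bridge_id = character(),
                        batch = character(), stringsAsFactors = FALSE)
  bmeta <- NULL
  if (nb > 0 && design$n_batches > 1) {
    bgroup <- rep(groups, length.out = nb)
    bage <- vapply(bgroup, function(g)
      stats::rnorm(1, design$age_dist[[g]][1], design$age_dist[[g]][2]),
      numeric(1))
    bsex <- vapply(bgroup, function(g)
      ifelse(stats::rbinom(1, 1, design$male_frac[[g]]) == 1, "M", "F"),
      character(1))
    bid <- sprintf("BR%02d", seq_len(nb))
    bsignal <- matrix(mu, nb, p, byrow = TRUE) +
      beta_by_group[bgroup, , drop = FALSE] +
      outer(bage - mean(age), a_slope) + outer(as.numeric(bsex == "M"), s_shift) +
      matrix(stats::rnorm(nb * p, 0, design$within_group_sd), nb, p)
    for (b in batches) {
      rows <- bsignal + batch_offset[rep(b, nb), , drop = FALSE]
      if (design$bridge_noise_sd > 0)
        rows <- rows + matrix(stats::rnorm(nb * p, 0, design$bridge_noise_sd),
                              nb, p)
      rownames(rows) <- paste(bid, b, sep = "_")
      bridge_rows <- rbind(bridge_rows, rows)
      bridges <- rbind(bridges, data.frame(
        sample_id = paste(bid, b, sep = "_"), bridge_id = bid, batch = b,
        stringsAsFactors = FALSE))
    }
    bmeta <- data.frame(
      sample_id = bridges$sample_id,
      diagnosis = rep(bgroup, design$n_batches),
      age = rep(bage, design$n_batches),
      sex = rep(bsex, design$n_batches),
      stringsAsFactors = FALSE)
  }

  all_values <- rbind(values, bridge_rows)
  all_batch <- c(batch, bridges$batch)
  names(all_batch) <- rownames(all_values)

  # LOD at a per-assay quantile of the cohort marginal distribution; planted
  # panel markers emulate assays with >90% detectability, so their censoring
  # quantile is capped at 0.10 (they must survive the 85% rule by design,
  # as the real panel was selected among assays that already passed it)
  q <- stats::runif(p, design$lod_quantile[1], design$lod_quantile[2])
  q[tag == "panel"] <- pmin(q[tag == "panel"], 0.10)
  lod <- vapply(seq_len(p), function(j)
    unname(stats::quantile(values[, j], q[j])), numeric(1))
  names(lod) <- assays
  if (mask_below_lod)
    all_values[sweep(all_values, 2, lod, "<")] <- NA_real_

  panel <- sub("^PROT\\d+_", "", assays)
  names(panel) <- assays
  m <- npx_matrix(all_values, lod = lod, batch = all_batch, panel = panel)

  metadata <- data.frame(
    sample_id = ids, diagnosis = diagnosis, age = age, sex = sex,
    cohort = "synthetic", is_bridge = FALSE, stringsAsFactors = FALSE)
  metadata <- add_clinical_covariates(metadata)
  if (!is.null(bmeta)) {
    bmeta$cohort <- "bridge"
    bmeta$is_bridge <- TRUE
    for (col in setdiff(names(metadata), names(bmeta))) bmeta[[col]] <- NA
    metadata <- rbind(metadata, bmeta[, names(metadata)])
  }

  truth <- data.frame(
    assay_id = assays, class = class,
    beta_dlb_vs_con = beta_dlb, beta_ad_vs_con = beta_ad,
    age_slope = a_slope, sex_shift = s_shift,
    is_panel = tag == "panel", tag = tag, stringsAsFactors = FALSE)

  list(npx = m, metadata = metadata, truth = truth, bridges = bridges,
       design = design, seed = seed)
}

# Plausible AD CSF biomarkers (pg/mL), MMSE and medication flags per group;
# Gaussian around typical group centers, for exercising correlation and
# sensitivity-analysis code paths only.
add_clinical_covariates <- function(meta) {
  centers <- list(
    # abeta42, ttau, ptau, mmse: (center, spread) per group
    CON = list(ab = c(1121, 160), tt = c(211, 70), pt = c(38, 11), mm = c(28, 2)),
    DLB = list(ab = c(764, 275), tt = c(297, 143), pt = c(52, 21), mm = c(22, 6)),
    AD  = list(ab = c(603, 91), tt = c(746, 319), pt = c(92, 27), mm = c(21, 5)))
  n <- nrow(meta)
  meta$abeta42 <- meta$ttau <- meta$ptau <- meta$mmse <- NA_real_
  for (g in names(centers)) {
    idx <- which(meta$diagnosis == g)
    cc <- centers[[g]]
    meta$abeta42[idx] <- pmax(stats::rnorm(length(idx), cc$ab[1], cc$ab[2]), 50)
    meta$ttau[idx] <- pmax(stats::rnorm(length(idx), cc$tt[1], cc$tt[2]), 20)
    meta$ptau[idx] <- pmax(stats::rnorm(length(idx), cc$pt[1], cc$pt[2]), 5)
    meta$mmse[idx] <- pmin(pmax(round(stats::rnorm(length(idx), cc$mm[1],
                                                   cc$mm[2])), 0), 30)
  }
  meta$parkinson_medication <- FALSE
  dlb <- which(meta$diagnosis == "DLB")
  if (length(dlb)) {
    med <- stats::runif(length(dlb))
    meta$parkinson_medication[dlb] <- med < 0.12
    meta$parkinson_medication[dlb[med > 0.67]] <- NA
  }
  meta$dlb_stage <- NA_integer_
  if (length(dlb))
    meta$dlb_stage[dlb] <- sample.int(4, length(dlb), replace = TRUE)
  meta
}

#' Write a generated cohort to plain-text files
#'
#' Emits the NPX long CSV and metadata CSV dialects read by
#' [read_npx_long()], the truth table as TSV, the bridge map as CSV and the
#' design as JSON.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_npx_long(sim$npx, file.path(dir, "npx_long.csv"))
  utils::write.csv(sim$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$bridges, file.path(dir, "bridges.csv"),
                   row.names = FALSE)
  design <- sim$design
  design$age_dist <- lapply(design$age_dist, unname)
  jsonlite::write_json(
    c(unclass(design), list(seed = sim$seed)),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
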