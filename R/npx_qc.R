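#' Filter assays by detectability
#'
#' Keeps an assay only if the fraction of its measured (non-missing) values
#' strictly above the assay's LOD is at least `min_frac` (default 85%).
#' Retained values below the LOD are kept unmodified: censoring the matrix
#' is deliberately not part of this step, matching common PEA practice of
#' carrying raw sub-LOD values into downstream statistics.
#'
#' Values exactly at the LOD count as not above it (strict inequality);
#' missing values are excluded from the denominator.
#'
#' @param m an [npx_matrix].
#' @param min_frac minimum detectable fraction in (0, 1].
#' @return a list with `matrix` (the filtered [npx_matrix]) and `dropped`
#'   (character vector of removed assay ids).
#' @export
filter_by_detectability <- function(m, min_frac = 0.85) {
  if (!inherits(m, "npx_matrix")) stopf("`m` must be an npx_matrix")
  if (!(min_frac > 0 && min_frac <= 1)) stopf("`min_frac` must be in (0, 1]")
  if (nrow(m$values) == 0 || ncol(m$values) == 0) stopf("empty NPX matrix")
  above <- sweep(m$values, 2, m$lod, ">")
  frac <- colSums(above, na.rm = TRUE) / colSums(!is.na(m$values))
  keep <- !is.na(frac) & frac >= min_frac
  list(matrix = m[, keep], dropped = assay_ids(m)[!keep])
}

#' Bridging-sample batch normalization
#'
#' Reference-sample normalization across measurement rounds: bridging
#' samples are aliquots re-measured in every batch; for each non-reference
#' batch and each assay the median over bridging samples of (value in that
#' batch minus value in the reference batch) is subtracted from all samples
#' of that batch. The reference batch is left unchanged. With `adjust =
#' "mean"` the mean of paired differences is used instead of the median.
#'
#' @param m an [npx_matrix] containing both cohort and bridge rows.
#' @param bridges a data.frame linking bridge measurements across batches,
#'   with columns `sample_id` (row of `m`) and `bridge_id` (the physical
#'   bridging sample); each `bridge_id` must appear in at least two batches.
#' @param reference_batch the batch whose level is taken as reference.
#' @param adjust `"median"` (default) or `"mean"` paired difference.
#' @return the normalized [npx_matrix].
#' @export
bridge_normalize <- function(m, bridges, reference_batch,
                             adjust = c("median", "mean")) {
  adjust <- match.arg(adjust)
  batches <- unique(m$batch)
  if (!reference_batch %in% batches)
    stopf("reference batch '%s' not present", reference_batch)
  if (length(batches) == 1) return(m)
  req <- c("sample_id", "bridge_id")
  if (!all(req %in% names(bridges)))
    stopf("`bridges` needs columns sample_id and bridge_id")
  absent <- setdiff(bridges$sample_id, sample_ids(m))
  if (length(absent))
    stopf("bridge rows missing from matrix: %s", paste(absent, collapse = ", "))
  stat <- if (adjust == "median") stats::median else mean

  bb <- bridges
  bb$batch <- m$batch[bb$sample_id]
  ref <- bb[bb$batch == reference_batch, ]
  v <- m$values
  for (b in setdiff(batches, reference_batch)) {
    cur <- bb[bb$batch == b, ]
    shared <- intersect(cur$bridge_id, ref$bridge_id)
    if (length(shared) == 0)
      stopf("no shared bridging samples between batch '%s' and reference '%s'",
            b, reference_batch)
    rows_b <- cur$sample_id[match(shared, cur$bridge_id)]
    rows_r <- ref$sample_id[match(shared, ref$bridge_id)]
    diffs <- v[rows_b, , drop = FALSE] - v[rows_r, , drop = FALSE]
    offset <- apply(diffs, 2, stat, na.rm = TRUE)
    offset[!is.finite(offset)] <- 0
    v[m$batch == b, ] <- sweep(v[m$batch == b, , drop = FALSE], 2, offset)
  }
  npx_matrix(v, lod = m$lod, batch = m$batch, panel = m$panel)
}

#' Correlation between replicate assays of the same protein
#'
#' Some proteins are measured by more than one PEA panel; agreement between
#' these replicate assays is a basic QC readout. For every assay pair mapped
#' to the same protein, the Spearman correlation is computed over samples
#' with both values present; pairs with fewer than 3 complete observations
#' are reported as `NA`.
#'
#' @param m an [npx_matrix].
#' @param replicate_map named list: protein symbol -> character vector of
#'   assay ids (each of length >= 2 and present in `m`).
#' @return data.frame with columns `protein`, `assay_1`, `assay_2`, `n`,
#'   `spearman_r`.
#' @export
replicate_correlation <- function(m, replicate_map) {
  out <- list()
  for (protein in names(replicate_map)) {
    assays <- replicate_map[[protein]]
    absent <- setdiff(assays, assay_ids(m))
    if (length(absent))
      stopf("replicate assays not in matrix for %s: %s", protein,
            paste(absent, collapse = ", "))
    if (length(assays) < 2)
      stopf("protein %s mapped to fewer than 2 assays", protein)
    pairs <- utils::combn(assays, 2)
    for (k in seq_len(ncol(pairs))) {
      a1 <- m$values[, pairs[1, k]]
      a2 <- m$values[, pairs[2, k]]
      ok <- !is.na(a1) & !is.na(a2)
      r <- if (sum(ok) >= 3)
        stats::cor(a1[ok], a2[ok], method = "spearman") else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        protein = protein, assay_1 = pairs[1, k], assay_2 = pairs[2, k],
        n = sum(ok), spearman_r = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Collapse replicate assays to one column per protein
#'
#' Optional step: replicate assays are carried as distinct columns through
#' differential abundance; this helper averages them when a single value per
#' protein is wanted.
#'
#' @inheritParams replicate_correlation
#' @return an [npx_matrix] in which each mapped protein's assays are
#'   replaced by their per-sample mean (LOD: mean of member LODs).
#' @export
collapse_replicates <- function(m, replicate_map) {
  v <- m$values
  lod <- m$lod
  drop <- character()
  for (protein in names(replicate_map)) {
    assays <- replicate_map[[protein]]
    collapsed <- rowMeans(v[, assays, drop = FALSE], na.rm = TRUE)
    collapsed[is.nan(collapsed)] <- NA_real_
    v[, assays[1]] <- collapsed
    colnames(v)[colnames(v) == assays[1]] <- protein
    lod_new <- mean(lod[assays])
    names(lod)[names(lod) == assays[1]] <- protein
    lod[protein] <- lod_new
    drop <- c(drop, assays[-1])
  }
  keep <- setdiff(colnames(v), drop)
  # panel identity is not meaningful for a cross-panel average
  npx_matrix(v[, keep, drop = FALSE], lod = lod[keep], batch = m$batch)
}
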