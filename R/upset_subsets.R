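#' Categorize one assay from its three significance flags
#'
#' Proteins nominally dysregulated between DLB and controls are partitioned
#' by their behavior in the other two pairwise contrasts:
#' * `dlb_unique` — also differs DLB vs AD but not AD vs CON (a DLB-specific
#'   change);
#' * `general_dementia` — does not differ between the dementias (regardless
#'   of the AD-vs-CON flag);
#' * `shared_divergent` — differs between dementias and AD also differs from
#'   controls;
#' * `unclassified` — fails the DLB-vs-CON gate.
#'
#' @param sig_dlb_con,sig_dlb_ad,sig_ad_con logical vectors of nominal
#'   (p < 0.05) significance flags, one element per assay.
#' @return character vector of subset labels.
#' @export
categorize_subset <- function(sig_dlb_con, sig_dlb_ad, sig_ad_con) {
  ifelse(!sig_dlb_con, "unclassified",
         ifelse(!sig_dlb_ad, "general_dementia",
                ifelse(sig_ad_con, "shared_divergent", "dlb_unique")))
}

#' Build the UpSet partition from three contrast tables
#'
#' Membership is defined at nominal significance (p < 0.05), not FDR.
#' Directions are the sign of the contrast beta (0 when beta is exactly 0 or
#' missing).
#'
#' @param tab_dlb_con,tab_dlb_ad,tab_ad_con results of [contrast_table()]
#'   for the DLB-vs-CON, DLB-vs-AD and AD-vs-CON contrasts (same assays).
#' @param p_threshold nominal significance threshold (default 0.05).
#' @return data.frame with per-assay flags (`sig_dlb_con`, `sig_dlb_ad`,
#'   `sig_ad_con`), `subset` label, and per-contrast direction columns.
#' @export
upset_partition <- function(tab_dlb_con, tab_dlb_ad, tab_ad_con,
                            p_threshold = 0.05) {
  assays <- tab_dlb_con$assay_id
  if (!setequal(assays, tab_dlb_ad$assay_id) ||
      !setequal(assays, tab_ad_con$assay_id))
    stopf("the three contrast tables must cover the same assays")
  i2 <- match(assays, tab_dlb_ad$assay_id)
  i3 <- match(assays, tab_ad_con$assay_id)
  sig <- function(tab) !is.na(tab$p) & tab$p < p_threshold
  flags <- data.frame(
    assay_id = assays,
    sig_dlb_con = sig(tab_dlb_con),
    sig_dlb_ad = sig(tab_dlb_ad)[i2],
    sig_ad_con = sig(tab_ad_con)[i3],
    stringsAsFactors = FALSE)
  flags$subset <- categorize_subset(flags$sig_dlb_con, flags$sig_dlb_ad,
                                    flags$sig_ad_con)
  flags$dir_dlb_con <- sign_or_zero(tab_dlb_con$beta)
  flags$dir_dlb_ad <- sign_or_zero(tab_dlb_ad$beta)[i2]
  flags$dir_ad_con <- sign_or_zero(tab_ad_con$beta)[i3]
  flags
}

sign_or_zero <- function(x) ifelse(is.na(x), 0, sign(x))

#' Subset sizes and percentages
#'
#' Counts the classified subsets and expresses each as a percentage of all
#' assays passing the DLB-vs-CON gate, rounded half up to integers.
#'
#' @param partition result of [upset_partition()].
#' @return data.frame with `subset`, `count`, `percent`.
#' @export
upset_counts <- function(partition) {
  labels <- c("dlb_unique", "general_dementia", "shared_divergent")
  counts <- vapply(labels, function(l) sum(partition$subset == l), integer(1))
  total <- sum(counts)
  percent <- if (total > 0) round_half_up(100 * counts / total) else
    rep(0, length(counts))
  data.frame(subset = labels, count = unname(counts),
             percent = unname(percent), stringsAsFactors = FALSE)
}

#' Per-subset direction-of-change summary
#'
#' For each UpSet subset, the median fold-change of its member proteins in
#' the DLB-vs-CON and AD-vs-CON contrasts, with a 95% percentile confidence
#' interval from bootstrap resampling of the member proteins. Subsets with
#' fewer than 3 members get an `NA` interval.
#'
#' @param partition result of [upset_partition()].
#' @param tab_dlb_con,tab_ad_con contrast tables supplying fold-changes.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with `subset`, `contrast`, `n`, `median_fc`,
#'   `ci_low`, `ci_high`.
#' @export
subset_direction_summary <- function(partition, tab_dlb_con, tab_ad_con,
                                     n_boot = 2000, seed = 1L) {
  set.seed(seed)
  labels <- c("dlb_unique", "general_dementia", "shared_divergent")
  tabs <- list(DLB_vs_CON = tab_dlb_con, AD_vs_CON = tab_ad_con)
  rows <- list()
  for (lab in labels) {
    members <- partition$assay_id[partition$subset == lab]
    if (length(members) == 0) next
    for (cn in names(tabs)) {
      fc <- tabs[[cn]]$fold_change[match(members, tabs[[cn]]$assay_id)]
      fc <- fc[!is.na(fc)]
      med <- stats::median(fc)
      if (length(fc) >= 3) {
        boots <- vapply(seq_len(n_boot), function(i)
          stats::median(sample(fc, replace = TRUE)), numeric(1))
        ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
      } else ci <- c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = lab, contrast = cn, n = length(fc), median_fc = med,
        ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' UpSet membership matrix
#'
#' A 0/1 membership matrix (assay x contrast) restricted to assays passing
#' the DLB-vs-CON gate, consumable by standard UpSet plotting tools.
#'
#' @param partition result of [upset_partition()].
#' @return data.frame with `assay_id` and one 0/1 column per contrast.
#' @export
upset_membership <- function(partition) {
  keep <- partition$sig_dlb_con
  data.frame(assay_id = partition$assay_id[keep],
             DLB_vs_CON = as.integer(partition$sig_dlb_con[keep]),
             DLB_vs_AD = as.integer(partition$sig_dlb_ad[keep]),
             AD_vs_CON = as.integer(partition$sig_ad_con[keep]),
             stringsAsFactors = FALSE)
}
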