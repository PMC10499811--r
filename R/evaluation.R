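#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney U statistic divided by `n1 * n0` (probability
#' that a random positive scores above a random negative, ties counted as
#' one half); the curve is built by a threshold sweep.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or two-level factor with the
#'   second level positive).
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr`,
#'   `threshold`), starting at (0, 0) and ending at (1, 1).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_group(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss[length(ss):1])[length(ss):1] # last index per threshold
  tpr <- cumsum(ys)[last] / n1
  fpr <- cumsum(1 - ys)[last] / n0
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, ss[last]))
  list(auc = unname(auc), curve = curve)
}

roc_summary <- function(auc, ci, method, n_resamples, seed, curve = NULL,
                        extra = NULL) {
  out <- list(auc = auc, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
              method = method, n_resamples = n_resamples, seed = seed,
              curve = curve)
  structure(c(out, extra), class = "roc_summary")
}

#' @exportS3Method base::print
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %s, %d resamples)\n",
              x$auc, x$ci_low, x$ci_high, x$method, x$n_resamples))
  invisible(x)
}

#' Bootstrap percentile confidence interval for an AUC
#'
#' Resampling is stratified within each class (preserving prevalence);
#' degenerate resamples cannot occur under stratification.
#'
#' @inheritParams roc_auc
#' @param B number of bootstrap resamples (>= 50; default 100).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return a `roc_summary` (`auc`, `ci_low`, `ci_high`, `method`,
#'   `n_resamples`, `seed`, `curve`).
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 100, seed = 1L,
                             conf = 0.95) {
  if (B < 50) stopf("B must be >= 50")
  y <- as_binary_group(labels)
  base <- roc_auc(scores, y)
  set.seed(seed)
  i1 <- which(y == 1); i0 <- which(y == 0)
  boots <- vapply(seq_len(B), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[idx], y[idx])$auc
  }, numeric(1))
  a <- (1 - conf) / 2
  roc_summary(base$auc, stats::quantile(boots, c(a, 1 - a)),
              "bootstrap_percentile", B, seed, base$curve)
}

#' Repeated k-fold cross-validated AUC of a ridge panel
#'
#' Internal validation of a marker panel: in every repeat the data are split
#' into stratified k folds; per fold, standardization and the ridge refit
#' are redone on the training part only and the held-out samples are scored
#' with the frozen fold model. Pooled held-out predictions give one AUC per
#' repeat; the summary is the mean AUC with a percentile interval over the
#' repeats (`pool = FALSE` averages per-fold AUCs instead).
#'
#' @param X numeric matrix of marker values (samples x markers).
#' @param y binary outcome.
#' @param covariates optional covariate matrix used in the fold refits.
#' @param k folds per repeat (default 5).
#' @param repeats number of repeats (default 1000).
#' @param penalty ridge penalty for the per-fold refits (default 0.1).
#' @param seed integer seed.
#' @param pool pool held-out predictions across folds (default) or average
#'   fold AUCs.
#' @return a `roc_summary` with `method = "repeated_cv_percentile"` and the
#'   per-repeat AUCs in `$repeat_aucs`.
#' @export
repeated_cv_auc <- function(X, y, covariates = NULL, k = 5, repeats = 1000,
                            penalty = 0.1, seed = 1L, pool = TRUE) {
  y <- as_binary_group(y)
  covariates <- as_covariate_matrix(covariates, nrow(X))
  seeds <- derive_seeds(seed, repeats)
  aucs <- vapply(seq_len(repeats), function(r) {
    folds <- make_stratified_folds(y, k, seeds[r])
    eta <- rep(NA_real_, length(y))
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- ridge_refit(X[tr, , drop = FALSE], y[tr],
                           covariates = if (!is.null(covariates))
                             covariates[tr, , drop = FALSE],
                           penalty = penalty)
      eta[!tr] <- predict(model, X[!tr, , drop = FALSE],
                          covariates = if (!is.null(covariates))
                            covariates[!tr, , drop = FALSE])
      fold_auc[f] <- roc_auc(eta[!tr], y[!tr])$auc
    }
    if (pool) roc_auc(eta, y)$auc else mean(fold_auc)
  }, numeric(1))
  roc_summary(mean(aucs), stats::quantile(aucs, c(0.025, 0.975)),
              "repeated_cv_percentile", repeats, seed,
              extra = list(repeat_aucs = aucs))
}

#' DeLong test for two paired AUCs
#'
#' Nonparametric comparison of two correlated ROC curves computed from
#' paired scores on the same samples, via the placement-value covariance
#' estimator; two-sided normal p-value.
#'
#' @param scores_1,scores_2 paired score vectors.
#' @param labels shared binary labels.
#' @return list with `auc_1`, `auc_2`, `z`, `p`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  y <- as_binary_group(labels)
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(y))
    stopf("scores and labels must be paired (equal length)")
  i1 <- which(y == 1); i0 <- which(y == 0)
  m <- length(i1); n <- length(i0)
  placements <- function(s) {
    # V10[i]: fraction of negatives below positive i (ties 1/2); V01 likewise
    v10 <- vapply(s[i1], function(xi)
      (sum(s[i0] < xi) + 0.5 * sum(s[i0] == xi)) / n, numeric(1))
    v01 <- vapply(s[i0], function(xj)
      (sum(s[i1] > xj) + 0.5 * sum(s[i1] == xj)) / m, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  p1 <- placements(scores_1); p2 <- placements(scores_2)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- p1$auc - p2$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(var_diff)
  list(auc_1 = p1$auc, auc_2 = p2$auc, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' External validation of a frozen panel model
#'
#' Applies a trained [ridge_refit()] model to a new cohort without any
#' refitting and summarizes discrimination for a diagnosis contrast with a
#' stratified bootstrap CI.
#'
#' @param model a `panel_model`.
#' @param m_new [npx_matrix] of the validation cohort (must contain all
#'   panel markers).
#' @param meta_new validation metadata.
#' @param group_a,group_b reference / positive diagnosis labels.
#' @param covariates metadata columns matching the model's training
#'   covariates (default age and sex when the model used covariates).
#' @param B,seed bootstrap settings (see [bootstrap_auc_ci()]).
#' @return a `roc_summary`.
#' @export
external_validate <- function(model, m_new, meta_new, group_a, group_b,
                              covariates = c("age", "sex"), B = 100,
                              seed = 1L) {
  absent <- setdiff(model$markers, assay_ids(m_new))
  if (length(absent))
    stopf("panel marker(s) absent from validation data: %s",
          paste(absent, collapse = ", "))
  meta_new <- validate_metadata(meta_new, m_new)
  meta_new <- meta_new[match(sample_ids(m_new), meta_new$sample_id), ]
  keep <- meta_new$diagnosis %in% c(group_a, group_b) &
    !(meta_new$is_bridge %||% FALSE)
  sub <- meta_new[keep, ]
  X <- m_new$values[keep, model$markers, drop = FALSE]
  covs <- if (length(model$covariate_coefficients))
    build_covariates(sub, covariates) else NULL
  scores <- predict(model, X, covariates = covs)
  y <- as.numeric(sub$diagnosis == group_b)
  bootstrap_auc_ci(scores, y, B = B, seed = seed)
}

#' Partial Spearman correlation matrix
#'
#' Rank-based correlations between variables conditioned on covariates: each
#' variable is rank-transformed, the ranks are residualized on the covariate
#' design (with intercept), and Pearson correlations of the residuals are
#' reported. Significance tiers are BH-adjusted over the upper triangle
#' (q < 0.05 / 0.01 / 0.001).
#'
#' @param vars data.frame or matrix of variables (columns correlated).
#' @param covariates optional covariate matrix/data.frame.
#' @param min_n minimum complete cases per pair (default 10).
#' @return list with matrices `r`, `p`, `q`, `n` and character matrix
#'   `tier` (`""`, `"*"`, `"**"`, `"***"`).
#' @export
partial_spearman_matrix <- function(vars, covariates = NULL, min_n = 10) {
  V <- as.matrix(vars)
  storage.mode(V) <- "double"
  p <- ncol(V)
  covariates <- as_covariate_matrix(covariates, nrow(V))
  nm <- colnames(V) %||% paste0("v", seq_len(p))
  r <- pm <- nmat <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  diag(r) <- 1
  q_cov <- if (is.null(covariates)) 1 else 1 + ncol(covariates)
  for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p)) {
    ok <- !is.na(V[, i]) & !is.na(V[, j])
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < min_n) next
    xi <- rank(V[ok, i]); xj <- rank(V[ok, j])
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    if (!is.null(covariates)) {
      qq <- qr(cbind(1, covariates[ok, , drop = FALSE]))
      xi <- qr.resid(qq, xi); xj <- qr.resid(qq, xj)
    }
    rho <- stats::cor(xi, xj)
    r[i, j] <- r[j, i] <- rho
    df <- n - 2 - (q_cov - 1)
    tstat <- rho * sqrt(df / (1 - rho^2))
    pm[i, j] <- pm[j, i] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  up <- upper.tri(pm)
  qv <- pm
  qv[up] <- bh_fdr(pm[up])
  qv[lower.tri(qv)] <- t(qv)[lower.tri(qv)]
  tier <- matrix("", p, p, dimnames = list(nm, nm))
  tier[!is.na(qv) & qv < 0.05] <- "*"
  tier[!is.na(qv) & qv < 0.01] <- "**"
  tier[!is.na(qv) & qv < 0.001] <- "***"
  list(r = r, p = pm, q = qv, n = nmat, tier = tier)
}

#' One-way ANOVA trend test across ordinal stages
#'
#' F-test of equal means across (ordered) stage groups, used for
#' NPX-vs-pathology-stage trend readouts.
#'
#' @param values numeric vector.
#' @param stage stage labels (factor/ordered/character); at least 2 stages
#'   with >= 2 observations each.
#' @return list with `f`, `df1`, `df2`, `p`.
#' @export
stage_trend_anova <- function(values, stage) {
  ok <- !is.na(values) & !is.na(stage)
  values <- values[ok]; stage <- factor(stage[ok])
  stage <- droplevels(stage)
  if (nlevels(stage) < 2) stopf("need at least 2 stages")
  if (any(table(stage) < 2)) stopf("every stage needs >= 2 observations")
  fit <- stats::oneway.test(values ~ stage, var.equal = TRUE)
  list(f = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = unname(fit$p.value))
}
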