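#' Nested linear-model test for one protein
#'
#' Differential abundance is assessed per protein by comparing two nested
#' linear models with protein abundance (log2 NPX) as the response: the base
#' model `y ~ 1 + covariates` against the extended model
#' `y ~ 1 + covariates + group`. The p-value is the exact F-test on the
#' model comparison (one added parameter), and the group coefficient of the
#' extended model is the log2 fold-change of the non-reference group.
#'
#' @param y numeric vector of protein values (log2 NPX); `NA`s are dropped
#'   (complete-case per protein); at least two observations per group must
#'   remain.
#' @param group binary group indicator: 0/1 numeric, logical, or a
#'   two-level factor (first level = reference).
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   columns (e.g. centered age and a 0/1 sex column).
#' @return list with `beta` (group coefficient), `se`, `p`, `n_used`.
#' @export
nested_lm_test <- function(y, group, covariates = NULL) {
  g <- as_binary_group(group)
  covariates <- as_covariate_matrix(covariates, length(y))
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- y[ok]; g <- g[ok]
  covariates <- if (!is.null(covariates)) covariates[ok, , drop = FALSE]
  if (min(table(factor(g, levels = 0:1))) < 2)
    stopf("need at least 2 samples per group after removing missing values")
  fit <- nested_f_fit(cbind(y), g, covariates)
  list(beta = unname(fit$beta[1]), se = unname(fit$se[1]),
       p = unname(fit$p[1]), n_used = length(y))
}

as_binary_group <- function(group) {
  if (is.factor(group)) {
    if (nlevels(droplevels(group)) != 2) stopf("`group` must have two levels")
    g <- as.numeric(group == levels(droplevels(group))[2])
  } else if (is.logical(group)) {
    g <- as.numeric(group)
  } else {
    u <- sort(unique(group[!is.na(group)]))
    if (length(u) == 1) stopf("`group` is constant")
    if (!all(u %in% c(0, 1))) stopf("numeric `group` must be coded 0/1")
    g <- as.numeric(group)
  }
  if (length(unique(g[!is.na(g)])) < 2) stopf("`group` is constant")
  g
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (nrow(x) != n) stopf("covariates must have one row per sample")
  if (is.null(colnames(x))) colnames(x) <- paste0("cov", seq_len(ncol(x)))
  x
}

# Vectorized nested F-test: Y is an n x p response matrix sharing one design.
# Returns per-column beta (group coefficient), se, p from the exact F-test of
# adding `group` to the covariate-only base model.
nested_f_fit <- function(Y, g, covariates = NULL) {
  n <- nrow(Y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  X1 <- cbind(X0, group = g)
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    aliased <- colnames(X1)[q1$pivot[seq.int(q1$rank + 1L, ncol(X1))]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(aliased, collapse = ", "))
  }
  q0 <- qr(X0)
  res1 <- qr.resid(q1, Y)
  res0 <- qr.resid(q0, Y)
  rss1 <- colSums(res1^2)
  rss0 <- colSums(res0^2)
  df1 <- n - ncol(X1)
  if (df1 <= 0) stopf("not enough samples for the extended model")
  fstat <- (rss0 - rss1) / (rss1 / df1)
  p <- stats::pf(fstat, 1, df1, lower.tail = FALSE)
  coefs <- qr.coef(q1, Y)
  beta <- coefs[ncol(X1), ]
  xtxi <- chol2inv(qr.R(q1))
  se <- sqrt(xtxi[ncol(X1), ncol(X1)] * rss1 / df1)
  list(beta = beta, se = se, p = p, df = df1)
}

# Nested logistic alternative: group ~ covariates (+ protein), LRT p-value;
# beta is the protein coefficient (log-odds per log2 NPX unit).
nested_logistic_fit <- function(y, g, covariates = NULL) {
  X0 <- if (is.null(covariates)) data.frame(g = g) else
    data.frame(g = g, covariates)
  fit0 <- stats::glm(g ~ ., data = X0, family = stats::binomial())
  X1 <- cbind(X0, protein = y)
  fit1 <- stats::glm(g ~ ., data = X1, family = stats::binomial())
  lrt <- fit0$deviance - fit1$deviance
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  sm <- summary(fit1)$coefficients
  list(beta = sm["protein", 1], se = sm["protein", 2], p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, applied per pairwise contrast over the number of
#' analyzed features.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed, ignored
#'   and returned as `NA`).
#' @return vector of BH-adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential abundance table for one pairwise contrast
#'
#' Fits the nested linear model for every assay of the matrix, contrasting
#' `group_b` against the reference `group_a` (positive beta = higher in
#' `group_b`), with age (centered) and sex (0/1) adjustment by default.
#' Missing protein values are handled complete-case per assay. Assays whose
#' fit fails are kept as rows with `NA` statistics and a reason code.
#'
#' @param m an [npx_matrix].
#' @param meta metadata data.frame (see [validate_metadata()]); bridge rows
#'   are excluded automatically.
#' @param group_a reference diagnosis label.
#' @param group_b non-reference diagnosis label.
#' @param covariates character vector of metadata columns to adjust for
#'   (default age and sex).
#' @param method `"linear"` (nested linear models, default) or `"logistic"`
#'   (diagnosis ~ covariates + protein, likelihood-ratio test; provided for
#'   sensitivity analysis — its beta is a log-odds ratio, not a log2
#'   fold-change).
#' @return data.frame with one row per assay: `assay_id`, `beta`, `se`, `p`,
#'   `q`, `fold_change` (`2^beta`), `n_used`, `sig_q05`, `sig_p05`,
#'   `reason`.
#' @export
contrast_table <- function(m, meta, group_a, group_b,
                           covariates = c("age", "sex"),
                           method = c("linear", "logistic")) {
  method <- match.arg(method)
  meta <- validate_metadata(meta, m)
  meta <- meta[match(sample_ids(m), meta$sample_id), ]
  keep <- meta$diagnosis %in% c(group_a, group_b) &
    !(meta$is_bridge %||% FALSE)
  if (!any(meta$diagnosis[keep] == group_a) ||
      !any(meta$diagnosis[keep] == group_b))
    stopf("both groups must be present (%s, %s)", group_a, group_b)
  sub <- meta[keep, ]
  Y <- m$values[keep, , drop = FALSE]
  g <- as.numeric(sub$diagnosis == group_b)
  covs <- build_covariates(sub, covariates)

  p <- ncol(Y)
  out <- data.frame(assay_id = colnames(Y), beta = NA_real_, se = NA_real_,
                    p = NA_real_, n_used = NA_integer_, reason = "",
                    stringsAsFactors = FALSE)
  complete <- !is.na(g) & (if (is.null(covs)) TRUE else
    stats::complete.cases(covs))
  no_na <- !anyNA(Y[complete, , drop = FALSE])
  if (method == "linear" && no_na) {
    fit <- nested_f_fit(Y[complete, , drop = FALSE], g[complete],
                        if (!is.null(covs)) covs[complete, , drop = FALSE])
    out$beta <- unname(fit$beta); out$se <- unname(fit$se)
    out$p <- unname(fit$p); out$n_used <- sum(complete)
  } else {
    for (j in seq_len(p)) {
      res <- tryCatch({
        if (method == "linear") {
          nested_lm_test(Y[, j], g, covs)
        } else {
          ok <- complete & !is.na(Y[, j])
          fit <- nested_logistic_fit(Y[ok, j], g[ok],
                                     if (!is.null(covs)) covs[ok, , drop = FALSE])
          c(fit, list(n_used = sum(ok)))
        }
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        out$reason[j] <- res
      } else {
        out$beta[j] <- res$beta; out$se[j] <- res$se
        out$p[j] <- res$p; out$n_used[j] <- res$n_used
      }
    }
  }
  out$q <- bh_fdr(out$p)
  out$fold_change <- 2^out$beta
  out$sig_q05 <- !is.na(out$q) & out$q < 0.05
  out$sig_p05 <- !is.na(out$p) & out$p < 0.05
  attr(out, "contrast") <- paste(group_b, "vs", group_a, sep = "_")
  out[, c("assay_id", "beta", "se", "p", "q", "fold_change", "n_used",
          "sig_q05", "sig_p05", "reason")]
}

build_covariates <- function(meta, covariates) {
  if (is.null(covariates) || length(covariates) == 0) return(NULL)
  missing <- setdiff(covariates, names(meta))
  if (length(missing))
    stopf("covariate column(s) not in metadata: %s",
          paste(missing, collapse = ", "))
  cols <- lapply(covariates, function(cv) {
    x <- meta[[cv]]
    if (cv == "sex") as.numeric(x == "M")
    else if (cv == "age") as.numeric(x) - mean(as.numeric(x), na.rm = TRUE)
    else if (is.character(x) || is.factor(x)) {
      f <- factor(x)
      if (nlevels(f) != 2)
        stopf("categorical covariate '%s' must have exactly 2 levels", cv)
      as.numeric(f == levels(f)[2])
    } else as.numeric(x)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- covariates
  x
}
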