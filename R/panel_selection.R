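#' @importFrom glmnet glmnet
NULL

standardize_features <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  if (any(scale == 0)) stopf("constant feature column(s): %s",
                             paste(colnames(X)[scale == 0], collapse = ", "))
  list(x = sweep(sweep(X, 2, center), 2, scale, "/"), center = center,
       scale = scale)
}

# Numerically stable binomial log-likelihood of 0/1 outcomes given the
# linear predictor.
binomial_loglik <- function(y, eta) {
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

#' Stratified cross-validation folds
#'
#' Assigns fold labels so that each fold's outcome group ratio is within one
#' sample of the full-data ratio (balanced/stratified k-fold CV).
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed controlling the assignment.
#' @return integer vector of fold labels in `1..k`.
#' @export
make_stratified_folds <- function(y, k = 10, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  tab <- table(y)
  if (length(tab) != 2) stopf("outcome must be binary")
  if (min(tab) < k) stopf("smallest class (%d) has fewer members than k = %d",
                          min(tab), k)
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in names(tab)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Analytic lambda_max: smallest penalty at which all penalized coefficients
# are zero, from the KKT condition at the covariate-only null fit.
lambda_max_enet <- function(xs, y, covariates = NULL, alpha) {
  n <- length(y)
  if (is.null(covariates)) {
    p0 <- rep(mean(y), n)
  } else {
    fit0 <- stats::glm.fit(cbind(1, covariates), y,
                           family = stats::binomial())
    p0 <- fit0$fitted.values
  }
  g <- abs(crossprod(xs, y - p0)) / n
  max(g) / max(alpha, 1e-3)
}

#' Elastic-net logistic regularization path
#'
#' Penalized logistic regression of a binary diagnosis contrast on
#' standardized protein features, with covariates (age, sex) and the
#' intercept left unpenalized. The objective is the binomial log-likelihood
#' minus `lambda * (alpha * ||b||_1 + (1 - alpha) * ||b||_2^2 / 2)` over the
#' protein coefficients. Path points whose number of nonzero protein
#' coefficients exceeds `cap` are discarded, reflecting the design goal of
#' small translatable marker panels.
#'
#' @param X numeric matrix of protein values (samples x assays, no missing
#'   values; assays failing detectability should already be removed).
#' @param y binary outcome (0/1, logical, or two-level factor; second level
#'   = positive class).
#' @param covariates optional numeric covariate matrix, unpenalized and not
#'   standardized.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (0 = ridge,
#'   1 = lasso).
#' @param lambda optional decreasing penalty grid; computed from the
#'   analytic `lambda_max` by default.
#' @param nlambda,lambda_min_ratio grid size and span when `lambda` is not
#'   given.
#' @param cap maximum number of selected proteins (default 21).
#' @param thresh glmnet convergence threshold.
#' @return list of candidates; each has `alpha`, `lambda`, `cap`,
#'   `selected_assays`, `coefficients` (standardized protein scale),
#'   `covariate_coefficients`, `intercept`, `n_nonzero`, `separation_flag`,
#'   plus shared `center`/`scale`/`lambda_grid` attributes.
#' @export
enet_logistic_path <- function(X, y, covariates = NULL, alpha,
                               lambda = NULL, nlambda = 100,
                               lambda_min_ratio = 1e-3, cap = 21,
                               thresh = 1e-9) {
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  if (anyNA(X)) stopf("X must not contain missing values")
  y <- as_binary_group(y)
  std <- standardize_features(X)
  covariates <- as_covariate_matrix(covariates, nrow(X))
  if (is.null(lambda)) {
    lmax <- lambda_max_enet(std$x, y, covariates, alpha)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  fit <- fit_enet(std$x, y, covariates, alpha, lambda, thresh)
  p <- ncol(X)
  beta <- as.matrix(fit$beta)[seq_len(p), , drop = FALSE]
  nnz <- colSums(beta != 0)
  sep <- apply(abs(beta), 2, max) > 30 # implausible on standardized log2 data
  keep <- which(nnz <= cap & !sep)
  candidates <- lapply(keep, function(i) {
    nz <- which(beta[, i] != 0)
    list(alpha = alpha, lambda = fit$lambda[i], cap = cap,
         selected_assays = colnames(X)[nz],
         coefficients = beta[nz, i],
         covariate_coefficients = if (!is.null(covariates))
           as.matrix(fit$beta)[-seq_len(p), i] else numeric(),
         intercept = fit$a0[i], n_nonzero = unname(nnz[i]),
         separation_flag = FALSE)
  })
  attr(candidates, "center") <- std$center
  attr(candidates, "scale") <- std$scale
  attr(candidates, "lambda_grid") <- lambda
  attr(candidates, "truncated") <- any(sep)
  candidates
}

fit_enet <- function(xs, y, covariates, alpha, lambda, thresh = 1e-9) {
  p <- ncol(xs)
  xx <- if (is.null(covariates)) xs else cbind(xs, covariates)
  pf <- c(rep(1, p), rep(0, if (is.null(covariates)) 0 else ncol(covariates)))
  # glmnet rescales penalty factors to sum to nvars; compensate so that the
  # nominal lambda keeps the textbook objective
  # loglik/n - lambda * (alpha ||b||_1 + (1 - alpha) ||b||_2^2 / 2)
  adjust <- sum(pf) / length(pf)
  fit <- glmnet::glmnet(xx, y, family = "binomial", alpha = alpha,
                        lambda = lambda * adjust, penalty.factor = pf,
                        standardize = FALSE, thresh = thresh, maxit = 1e6)
  fit$lambda <- fit$lambda / adjust
  fit
}

#' Tune the elastic net over a (alpha, cap) grid by stratified CV
#'
#' For every cell of the mixing-parameter x marker-cap grid, the penalty
#' strength is chosen by balanced (outcome-stratified) k-fold
#' cross-validation of the held-out binomial log-likelihood, restricted to
#' penalties whose full-data fit selects at most `cap` proteins. Each cell's
#' winning candidate is refit on the full data and annotated with its
#' cross-validated AUC (pooled held-out predictions).
#'
#' @inheritParams enet_logistic_path
#' @param alpha_grid mixing parameters to scan.
#' @param cap_grid marker-count caps to scan (21 = largest panel entertained).
#' @param k number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param rule `"max"` picks the penalty maximizing mean held-out
#'   log-likelihood; `"1se"` the sparsest penalty within one standard error
#'   of that maximum.
#' @return object of class `panel_tuning`: list with `candidates` (one per
#'   grid cell, each carrying `cv_loglik`, `cv_auc`, `center`, `scale`),
#'   `folds`, `seed`, `grid`.
#' @export
cv_tune <- function(X, y, covariates = NULL,
                    alpha_grid = seq(0.1, 1, by = 0.1),
                    cap_grid = c(3, 5, 7, 10, 15, 21),
                    k = 10, nlambda = 100, lambda_min_ratio = 1e-3,
                    seed = 1L, rule = c("max", "1se")) {
  rule <- match.arg(rule)
  y <- as_binary_group(y)
  covariates <- as_covariate_matrix(covariates, nrow(X))
  folds <- make_stratified_folds(y, k, seed)
  std <- standardize_features(X)
  p <- ncol(X)
  candidates <- list()
  for (alpha in alpha_grid) {
    lmax <- lambda_max_enet(std$x, y, covariates, alpha)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
    full <- fit_enet(std$x, y, covariates, alpha, lambda)
    beta_full <- as.matrix(full$beta)
    nnz <- colSums(beta_full[seq_len(p), , drop = FALSE] != 0)

    # held-out linear predictors for every (sample, lambda)
    eta_ho <- matrix(NA_real_, nrow(X), length(lambda))
    for (f in seq_len(k)) {
      tr <- folds != f
      # refit standardization inside the fold to avoid leakage
      stdf <- standardize_features(X[tr, , drop = FALSE])
      fitf <- fit_enet(stdf$x, y[tr],
                       if (!is.null(covariates)) covariates[tr, , drop = FALSE],
                       alpha, lambda)
      xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, stdf$center), 2,
                   stdf$scale, "/")
      xte <- if (is.null(covariates)) xte else
        cbind(xte, covariates[!tr, , drop = FALSE])
      eta <- cbind(1, xte) %*% rbind(fitf$a0, as.matrix(fitf$beta))
      eta_ho[!tr, seq_len(ncol(eta))] <- eta
    }
    ok_l <- colSums(is.na(eta_ho)) == 0
    mean_ll <- rep(-Inf, length(lambda))
    fold_se <- rep(NA_real_, length(lambda))
    for (i in which(ok_l)) {
      per_fold <- vapply(seq_len(k), function(f) {
        te <- folds == f
        binomial_loglik(y[te], eta_ho[te, i]) / sum(te)
      }, numeric(1))
      mean_ll[i] <- binomial_loglik(y, eta_ho[, i]) / length(y)
      fold_se[i] <- stats::sd(per_fold) / sqrt(k)
    }
    for (cap in cap_grid) {
      eligible <- which(nnz <= cap & is.finite(mean_ll))
      if (length(eligible) == 0) next
      best <- eligible[which.max(mean_ll[eligible])]
      if (rule == "1se") {
        thr <- mean_ll[best] - fold_se[best]
        best <- eligible[eligible <= best & mean_ll[eligible] >= thr][1]
      }
      nz <- which(beta_full[seq_len(p), best] != 0)
      cand <- list(
        alpha = alpha, cap = cap, lambda = lambda[best],
        lambda_grid = lambda,
        selected_assays = colnames(X)[nz],
        coefficients = beta_full[nz, best],
        covariate_coefficients = if (!is.null(covariates))
          beta_full[-seq_len(p), best] else numeric(),
        intercept = full$a0[best],
        n_nonzero = unname(nnz[best]),
        cv_loglik = mean_ll[best],
        cv_auc = roc_auc(eta_ho[, best], y)$auc,
        center = std$center, scale = std$scale)
      candidates[[length(candidates) + 1L]] <- cand
    }
  }
  if (length(candidates) == 0) stopf("no eligible candidates on the grid")
  structure(list(candidates = candidates, folds = folds, seed = seed,
                 k = k, rule = rule,
                 grid = list(alpha = alpha_grid, cap = cap_grid)),
            class = "panel_tuning")
}

#' Summarize a tuning grid
#'
#' @param tuning result of [cv_tune()].
#' @return data.frame with one row per grid cell: `alpha`, `cap`, `lambda`,
#'   `n_markers`, `cv_loglik`, `cv_auc`.
#' @export
tuning_summary <- function(tuning) {
  do.call(rbind, lapply(tuning$candidates, function(cc)
    data.frame(alpha = cc$alpha, cap = cc$cap, lambda = cc$lambda,
               n_markers = cc$n_nonzero, cv_loglik = cc$cv_loglik,
               cv_auc = cc$cv_auc)))
}

#' Select the final candidate from a tuning grid
#'
#' Lexicographic rule: highest cross-validated AUC (to a tolerance, since
#' resampled AUCs are noisy), then fewest selected markers, then smaller
#' mixing parameter (stronger decorrelation), then larger penalty.
#'
#' @param tuning result of [cv_tune()], or a bare list of candidates.
#' @param auc_tol AUC tolerance within which candidates count as tied
#'   (default 0.005).
#' @return the chosen candidate (list).
#' @export
choose_model <- function(tuning, auc_tol = 0.005) {
  cands <- if (inherits(tuning, "panel_tuning")) tuning$candidates else tuning
  if (length(cands) == 0) stopf("no candidates to choose from")
  auc <- vapply(cands, function(cc) cc$cv_auc, numeric(1))
  nm <- vapply(cands, function(cc) length(cc$selected_assays), numeric(1))
  al <- vapply(cands, function(cc) cc$alpha, numeric(1))
  lm <- vapply(cands, function(cc) cc$lambda, numeric(1))
  tied <- which(auc >= max(auc) - auc_tol)
  tied <- tied[order(nm[tied], al[tied], -lm[tied])]
  cands[[tied[1]]]
}

#' Fold-based selection proportions
#'
#' Stability analysis of a tuned candidate: the model is refit on each of
#' the k training folds (same stratified folds as the tuning seed) at the
#' candidate's penalty, and each assay's selection proportion is the
#' fraction of folds in which its coefficient is nonzero. Stable markers are
#' those selected in (almost) every fold.
#'
#' @inheritParams cv_tune
#' @param candidate a candidate from [cv_tune()]/[choose_model()] (uses its
#'   `alpha`, `lambda` and `lambda_grid`).
#' @return named numeric vector of per-assay proportions in `[0, 1]`.
#' @export
selection_proportions <- function(X, y, covariates = NULL, candidate,
                                  k = 10, seed = 1L) {
  y <- as_binary_group(y)
  covariates <- as_covariate_matrix(covariates, nrow(X))
  folds <- make_stratified_folds(y, k, seed)
  p <- ncol(X)
  counts <- numeric(p)
  idx <- which.min(abs(candidate$lambda_grid - candidate$lambda))
  for (f in seq_len(k)) {
    tr <- folds != f
    stdf <- standardize_features(X[tr, , drop = FALSE])
    fitf <- fit_enet(stdf$x, y[tr],
                     if (!is.null(covariates)) covariates[tr, , drop = FALSE],
                     candidate$alpha, candidate$lambda_grid)
    b <- as.matrix(fitf$beta)[seq_len(p), min(idx, ncol(fitf$beta))]
    counts <- counts + (b != 0)
  }
  stats::setNames(counts / k, colnames(X))
}

#' Ridge refit of a selected marker panel
#'
#' After manual/stable marker extraction, the final logistic signature is
#' re-estimated under a ridge penalty (default 0.1 on standardized marker
#' coefficients; covariates and intercept unpenalized) to temper
#' post-selection overfitting. Coefficients are returned on the original
#' NPX scale.
#'
#' @param X numeric matrix containing (at least) the marker columns.
#' @param y binary outcome.
#' @param markers character vector of marker assay ids (columns of `X`).
#' @param covariates optional covariate matrix, unpenalized.
#' @param penalty ridge penalty strength lambda (default 0.1).
#' @param contrast optional label recording the training contrast.
#' @return object of class `panel_model`: `markers`, `intercept`,
#'   `coefficients` (original scale), `coefficients_std` (standardized
#'   scale), `covariate_coefficients`, `center`, `scale`, `penalty`,
#'   `contrast`.
#' @export
ridge_refit <- function(X, y, markers = colnames(X), covariates = NULL,
                        penalty = 0.1, contrast = NULL) {
  if (length(markers) < 1) stopf("need at least one marker")
  absent <- setdiff(markers, colnames(X))
  if (length(absent)) stopf("marker(s) not in X: %s",
                            paste(absent, collapse = ", "))
  y <- as_binary_group(y)
  covariates <- as_covariate_matrix(covariates, nrow(X))
  Xm <- X[, markers, drop = FALSE]
  std <- standardize_features(Xm)
  # glmnet needs >= 2 columns; pad ridge fits of a single marker
  pad <- ncol(std$x) == 1
  xfit <- if (pad) cbind(std$x, .pad. = 0) else std$x
  fit <- fit_enet(xfit, y, covariates, alpha = 0,
                  lambda = c(penalty * 1.01, penalty), thresh = 1e-11)
  b <- as.matrix(fit$beta)[, 2]
  a0 <- fit$a0[2]
  pm <- length(markers)
  beta_std <- b[seq_len(pm)]
  cov_coef <- if (is.null(covariates)) numeric() else
    b[seq.int(pm + (if (pad) 2 else 1), length(b))]
  beta_orig <- beta_std / std$scale
  intercept <- a0 - sum(beta_std * std$center / std$scale)
  structure(list(markers = markers, intercept = unname(intercept),
                 coefficients = stats::setNames(unname(beta_orig), markers),
                 coefficients_std = stats::setNames(unname(beta_std), markers),
                 covariate_coefficients = cov_coef,
                 center = std$center, scale = std$scale,
                 penalty = penalty, contrast = contrast),
            class = "panel_model")
}

#' @exportS3Method base::print
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d marker(s), ridge penalty %.3g%s\n",
              length(x$markers), x$penalty,
              if (!is.null(x$contrast)) paste0(", contrast ", x$contrast) else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score new samples with a fitted panel model
#'
#' Applies the frozen coefficients: no refitting. Covariate columns must be
#' supplied if the model was trained with covariates.
#'
#' @param object a [ridge_refit()] `panel_model`.
#' @param newdata numeric matrix containing the model's marker columns.
#' @param covariates covariate matrix aligned with `newdata` rows.
#' @param type `"link"` (linear predictor) or `"response"` (probability).
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.panel_model <- function(object, newdata, covariates = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  absent <- setdiff(object$markers, colnames(newdata))
  if (length(absent))
    stopf("marker(s) absent from new data: %s", paste(absent, collapse = ", "))
  eta <- object$intercept +
    as.matrix(newdata[, object$markers, drop = FALSE]) %*% object$coefficients
  if (length(object$covariate_coefficients)) {
    if (is.null(covariates))
      stopf("model was trained with covariates; supply them")
    covariates <- as_covariate_matrix(covariates, nrow(newdata))
    eta <- eta + covariates %*% object$covariate_coefficients
  }
  eta <- drop(eta)
  if (type == "response") stats::plogis(eta) else eta
}

#' Serialize / deserialize a panel model as JSON
#'
#' Full double precision is preserved so that a round trip reproduces the
#' model exactly.
#'
#' @param model a `panel_model`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `panel_model_to_json`: the path or JSON string;
#'   `panel_model_from_json`: the restored `panel_model`.
#' @export
panel_model_to_json <- function(model, path = NULL) {
  x <- unclass(model)
  # named numeric vectors become JSON objects; 17 significant digits give an
  # exact double round trip
  for (f in c("coefficients", "coefficients_std", "center", "scale",
              "covariate_coefficients"))
    if (length(x[[f]])) x[[f]] <- as.list(x[[f]])
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname panel_model_to_json
#' @param json a file path or JSON string produced by
#'   [panel_model_to_json()].
#' @export
panel_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  for (f in c("coefficients", "coefficients_std", "center", "scale"))
    x[[f]] <- unlist(x[[f]])
  x$covariate_coefficients <- unlist(x$covariate_coefficients) %||% numeric()
  out <- list(markers = x$markers, intercept = x$intercept,
              coefficients = x$coefficients,
              coefficients_std = x$coefficients_std,
              covariate_coefficients = x$covariate_coefficients,
              center = x$center, scale = x$scale, penalty = x$penalty,
              contrast = x$contrast)
  structure(out, class = "panel_model")
}
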