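# Small deterministic classification problem with two informative features.
panel_toy <- function(n = 200, p = 12, beta = c(1.2, -1), seed = 30) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("a%02d", seq_len(p))))
  eta <- X[, 1] * beta[1] + X[, 2] * beta[2]
  y <- rbinom(n, 1, plogis(eta))
  covs <- cbind(age = rnorm(n, 0, 8), sex = rbinom(n, 1, 0.5))
  list(X = X, y = y, covs = covs)
}

test_that("the analytic lambda_max zeroes the whole path (KKT at the null fit)", {
  d <- panel_toy()
  for (alpha in c(0.5, 1)) {
    # independent computation of lambda_max from the null-model gradient
    xs <- scale(d$X)
    p0 <- rep(mean(d$y), nrow(d$X))
    lmax <- max(abs(crossprod(xs, d$y - p0))) / nrow(d$X) / alpha
    cands <- enet_logistic_path(d$X, d$y, alpha = alpha,
                                lambda = c(2 * lmax, lmax * 1.0001))
    expect_true(all(vapply(cands, function(cc) cc$n_nonzero, numeric(1)) == 0))
  }
})

test_that("pure ridge never sparsifies; strong feature enters the path first", {
  d <- panel_toy()
  cands <- enet_logistic_path(d$X, d$y, alpha = 0, nlambda = 8,
                              cap = ncol(d$X))
  nnz <- vapply(cands, function(cc) cc$n_nonzero, numeric(1))
  expect_true(all(nnz[-1] == ncol(d$X))) # all nonzero for any finite penalty

  set.seed(31)
  X <- matrix(rnorm(150 * 50), 150, 50,
              dimnames = list(NULL, sprintf("n%02d", 1:50)))
  X[, 25] <- X[, 25] + 2.5 * rep(0:1, length.out = 150)
  y <- rep(0:1, length.out = 150)
  cands <- enet_logistic_path(X, y, alpha = 1, nlambda = 60)
  first <- cands[[which(vapply(cands, function(cc) cc$n_nonzero, numeric(1)) > 0)[1]]]
  expect_equal(first$selected_assays, "n25")
})

test_that("returned solutions satisfy the elastic-net KKT conditions", {
  d <- panel_toy(n = 150, p = 8)
  alpha <- 0.7
  cands <- enet_logistic_path(d$X, d$y, covariates = d$covs, alpha = alpha,
                              nlambda = 20, cap = 8, thresh = 1e-13)
  xs <- sweep(sweep(d$X, 2, attr(cands, "center")), 2, attr(cands, "scale"), "/")
  for (cc in cands[c(5, 10, 15, 20)]) {
    beta <- numeric(ncol(d$X))
    names(beta) <- colnames(d$X)
    beta[cc$selected_assays] <- cc$coefficients
    eta <- cc$intercept + xs %*% beta + d$covs %*% cc$covariate_coefficients
    g <- crossprod(xs, d$y - plogis(eta)) / nrow(d$X) # score of the unpenalized loglik / n
    lam <- cc$lambda
    zero <- beta == 0
    expect_true(all(abs(g[zero]) <= lam * alpha + 1e-6))
    if (any(!zero))
      expect_lt(max(abs(g[!zero] - (lam * alpha * sign(beta[!zero]) +
                                      lam * (1 - alpha) * beta[!zero]))),
                1e-6) # absolute gradient tolerance
  }
})

test_that("every emitted candidate respects its cap", {
  d <- panel_toy(n = 120, p = 30, seed = 33)
  for (cap in c(3, 10)) {
    cands <- enet_logistic_path(d$X, d$y, alpha = 1, nlambda = 40, cap = cap)
    expect_true(all(vapply(cands, function(cc) cc$n_nonzero, numeric(1)) <= cap))
  }
})

test_that("stratified folds balance outcome ratios and are seed-deterministic", {
  y <- rep(c(0, 1), c(70, 30))
  folds <- make_stratified_folds(y, k = 10, seed = 2)
  for (f in 1:10) {
    expect_equal(sum(y == 1 & folds == f), 3)
    expect_equal(sum(y == 0 & folds == f), 7)
  }
  expect_identical(folds, make_stratified_folds(y, 10, seed = 2))
  expect_false(identical(folds, make_stratified_folds(y, 10, seed = 3)))
  expect_error(make_stratified_folds(rep(c(0, 1), c(95, 5)), k = 10),
               "fewer members")
})

test_that("cv_tune is deterministic and the chooser applies its lexicographic rule", {
  d <- panel_toy(n = 160, p = 15, seed = 34)
  t1 <- cv_tune(d$X, d$y, d$covs, alpha_grid = c(0.5, 1), cap_grid = c(3, 8),
                k = 5, nlambda = 30, seed = 7)
  t2 <- cv_tune(d$X, d$y, d$covs, alpha_grid = c(0.5, 1), cap_grid = c(3, 8),
                k = 5, nlambda = 30, seed = 7)
  expect_identical(t1$folds, t2$folds)
  expect_equal(choose_model(t1)$lambda, choose_model(t2)$lambda)

  fake <- function(auc, n, alpha = 0.5) list(cv_auc = auc, alpha = alpha,
                                             lambda = 0.1, cap = 21,
                                             selected_assays = sprintf("m%d", seq_len(n)))
  expect_equal(length(choose_model(list(fake(0.93, 7), fake(0.93, 12)))$selected_assays), 7)
  expect_equal(length(choose_model(list(fake(0.95, 10), fake(0.90, 3)))$selected_assays), 10)
  single <- fake(0.8, 4)
  expect_identical(choose_model(list(single)), single)
})

test_that("pure-noise features tune to chance-level cross-validated AUC", {
  set.seed(35)
  X <- matrix(rnorm(300 * 25), 300, 25,
              dimnames = list(NULL, sprintf("n%02d", 1:25)))
  y <- rbinom(300, 1, 0.5)
  tuned <- cv_tune(X, y, alpha_grid = 1, cap_grid = 5, k = 10, nlambda = 25,
                   seed = 8)
  expect_lt(abs(choose_model(tuned)$cv_auc - 0.5), 0.08)
})

test_that("selection proportions flag a planted strong marker as fully stable", {
  set.seed(36)
  n <- 150
  X <- matrix(rnorm(n * 30, sd = 0.5), n, 30,
              dimnames = list(NULL, sprintf("m%02d", 1:30)))
  g <- rep(0:1, length.out = n)
  X[, 7] <- X[, 7] + 0.95 * g
  tuned <- cv_tune(X, g, alpha_grid = 1, cap_grid = 3, k = 10, nlambda = 30,
                   seed = 9)
  chosen <- choose_model(tuned)
  props <- selection_proportions(X, g, candidate = chosen, k = 10, seed = 9)
  expect_equal(unname(props["m07"]), 1.0)
  expect_true(all(props >= 0 & props <= 1))
  expect_gte(sum(props == 0), 20) # most noise assays never enter
})

test_that("ridge refit shrinks, stays finite under separation, and hits its limits", {
  d <- panel_toy(n = 200, p = 4, seed = 37)
  # huge penalty: marker coefficients -> 0, intercept -> log-odds prevalence
  big <- ridge_refit(d$X, d$y, penalty = 1e6)
  expect_true(all(abs(big$coefficients) < 1e-3))
  expect_equal(big$intercept, qlogis(mean(d$y)), tolerance = 0.01)

  # shrinkage relative to the unpenalized MLE
  mle <- stats::glm(d$y ~ scale(d$X), family = stats::binomial())
  pen <- ridge_refit(d$X, d$y, penalty = 0.1)
  expect_lt(sqrt(sum(pen$coefficients_std^2)),
            sqrt(sum(stats::coef(mle)[-1]^2)))

  # separable toy data stays finite
  Xs <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
               dimnames = list(NULL, "sep"))
  ys <- rep(0:1, each = 20)
  fit <- ridge_refit(Xs, ys, penalty = 0.1)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
})

test_that("panel models serialize exactly and score new data with frozen coefficients", {
  d <- panel_toy(n = 180, p = 6, seed = 38)
  pm <- ridge_refit(d$X, d$y, markers = c("a01", "a02", "a05"),
                    covariates = d$covs, penalty = 0.1, contrast = "DLB_vs_AD")
  path <- withr::local_tempfile(fileext = ".json")
  panel_model_to_json(pm, path)
  pm2 <- panel_model_from_json(path)
  expect_identical(unclass(pm), unclass(pm2))

  # linear predictor matches the explicit arithmetic
  eta <- predict(pm, d$X, covariates = d$covs)
  manual <- pm$intercept + d$X[, pm$markers] %*% pm$coefficients +
    d$covs %*% pm$covariate_coefficients
  expect_equal(eta, drop(manual), tolerance = 1e-12, ignore_attr = TRUE)
  pr <- predict(pm, d$X, covariates = d$covs, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  expect_error(predict(pm, d$X[, -1]), "absent")
})
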