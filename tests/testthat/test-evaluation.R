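# Brute-force AUC: all-pairs concordance with ties counted 1/2.
brute_auc <- function(scores, y) {
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("roc_auc equals hand counting and brute-force concordance", {
  res <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(res$auc, 0.75) # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5) # all ties

  set.seed(40)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    expect_equal(roc_auc(scores, y)$auc, brute_auc(scores, y))
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1); AUC is rank-invariant", {
  set.seed(41)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  curve <- roc_auc(s, y)$curve
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1); expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  expect_equal(roc_auc(exp(3 * s) + 5, y)$auc, roc_auc(s, y)$auc)
})

test_that("stratified bootstrap CIs behave at the extremes and reproduce under a seed", {
  y <- rep(0:1, each = 20)
  s <- c(rnorm(20, 0), rnorm(20, 10))
  b <- bootstrap_auc_ci(s, y, B = 100, seed = 1)
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  set.seed(99) # outside seed must not matter
  b2 <- bootstrap_auc_ci(s, y, B = 100, seed = 1)
  expect_identical(b[c("auc", "ci_low", "ci_high")],
                   b2[c("auc", "ci_low", "ci_high")])
  expect_error(bootstrap_auc_ci(s, y, B = 10), "B must be")
})

test_that("bootstrap CI width is consistent with the Hanley-McNeil analytic SE", {
  set.seed(42)
  n1 <- 250; n0 <- 250
  s <- c(rnorm(n0, 0), rnorm(n1, 1))
  y <- rep(0:1, c(n0, n1))
  b <- bootstrap_auc_ci(s, y, B = 300, seed = 2)
  a <- roc_auc(s, y)$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  analytic_width <- 2 * qnorm(0.975) * se
  expect_lt(abs((b$ci_high - b$ci_low) - analytic_width) / analytic_width, 0.25)
})

test_that("DeLong: identical or monotone-transformed scores give p = 1", {
  set.seed(43)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + y
  d1 <- delong_test(s, s, y)
  expect_equal(d1$z, 0); expect_equal(d1$p, 1)
  d2 <- delong_test(s, exp(s), y) # AUC is rank-based
  expect_equal(d2$p, 1)
  expect_equal(d2$auc_1, d2$auc_2)
})

test_that("DeLong p agrees with a paired-permutation oracle", {
  set.seed(44)
  n <- 120
  y <- rep(0:1, each = n / 2)
  latent <- rnorm(n) + 0.9 * y
  s1 <- latent + rnorm(n, sd = 0.6)
  s2 <- latent + rnorm(n, sd = 0.9)
  dl <- delong_test(s1, s2, y)
  # permutation oracle: swap the paired scores sample-wise at random
  perms <- 4000
  d_obs <- abs(roc_auc(s1, y)$auc - roc_auc(s2, y)$auc)
  set.seed(45)
  d_null <- vapply(seq_len(perms), function(b) {
    sw <- runif(n) < 0.5
    a <- ifelse(sw, s2, s1)
    bb <- ifelse(sw, s1, s2)
    abs(roc_auc(a, y)$auc - roc_auc(bb, y)$auc)
  }, numeric(1))
  p_perm <- mean(d_null >= d_obs)
  expect_lt(abs(dl$p - p_perm), 0.03)
})

test_that("repeated CV reduces to one stratified k-fold at repeats = 1 and is chance-level on noise", {
  set.seed(46)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- rbinom(200, 1, 0.5)
  one <- repeated_cv_auc(X, y, k = 5, repeats = 1, seed = 3)
  expect_length(one$repeat_aucs, 1)
  expect_equal(one$auc, one$repeat_aucs[1])

  cv <- repeated_cv_auc(X, y, k = 5, repeats = 30, seed = 3)
  expect_gt(cv$auc, 0.40); expect_lt(cv$auc, 0.60)
  expect_lte(cv$ci_low, cv$auc); expect_gte(cv$ci_high, cv$auc)

  # doubling the repeats leaves the mean inside the smaller run's CI
  cv2 <- repeated_cv_auc(X, y, k = 5, repeats = 60, seed = 3)
  expect_gte(cv2$auc, cv$ci_low); expect_lte(cv2$auc, cv$ci_high)
})

test_that("external validation freezes coefficients and checks marker presence", {
  d <- small_design()
  sim <- generate_cohort(d, seed = 50)
  planted <- sim$truth$assay_id[sim$truth$is_panel]
  tr <- contrast_xy(sim, "AD", "DLB", assays = planted)
  pm <- ridge_refit(tr$X, tr$y, covariates = tr$covs, penalty = 0.1,
                    contrast = "DLB_vs_AD")

  # validating on the training cohort reproduces the training AUC exactly
  meta <- sim$metadata
  cohort <- meta[!meta$is_bridge, ]
  val <- external_validate(pm, sim$npx[cohort$sample_id, ], cohort,
                           "AD", "DLB", B = 60, seed = 4)
  train_auc <- roc_auc(predict(pm, tr$X, covariates = tr$covs), tr$y)$auc
  expect_equal(val$auc, train_auc, tolerance = 1e-12)

  # an independent cohort from the same design scores close to training
  sim2 <- generate_cohort(d, seed = 51)
  cohort2 <- sim2$metadata[!sim2$metadata$is_bridge, ]
  val2 <- external_validate(pm, sim2$npx[cohort2$sample_id, ], cohort2,
                            "AD", "DLB", B = 60, seed = 4)
  expect_gt(val2$auc, train_auc - 0.12)

  expect_error(external_validate(pm, sim2$npx[cohort2$sample_id,
                                              setdiff(assay_ids(sim2$npx), planted[1])],
                                 cohort2, "AD", "DLB"),
               "absent.*")
})

test_that("partial Spearman correlations condition out covariates", {
  set.seed(52)
  n <- 400
  z <- rnorm(n)
  vars <- data.frame(x = rnorm(n), y = z + rnorm(n, sd = 0.3), w = rnorm(n))
  vars$ident <- vars$x
  res0 <- partial_spearman_matrix(vars[, c("x", "ident")])
  expect_equal(res0$r["x", "ident"], 1)

  res <- partial_spearman_matrix(vars[, c("x", "y", "w")],
                                 covariates = cbind(z = z))
  expect_lt(abs(res$r["x", "y"]), 0.15) # y is covariate-driven
  expect_true(isSymmetric(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 3))
  # marginal (unconditioned) correlation with the covariate-driven y is absent
  # by design here; tiers use BH over the upper triangle
  expect_true(all(res$tier %in% c("", "*", "**", "***")))
})

test_that("stage trend ANOVA matches the two-sample t-test and flags strong trends", {
  set.seed(53)
  v <- rnorm(40)
  g <- rep(c("s1", "s2"), each = 20)
  res <- stage_trend_anova(v, g)
  tt <- t.test(v[g == "s1"], v[g == "s2"], var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-12)

  stages <- rep(1:4, each = 25)
  trend <- stages * 2 + rnorm(100, sd = 0.5)
  expect_lt(stage_trend_anova(trend, stages)$p, 1e-6)
  expect_error(stage_trend_anova(rnorm(10), rep(1, 10)), "2 stages")
})
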