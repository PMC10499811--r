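#' Passing-Bablok method-comparison regression
#'
#' Robust, scale-equivariant regression line between two measurement
#' platforms. The slope is the shifted median of all pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)` over pairs `i < j`: slopes of exactly -1 are
#' excluded, pairs with equal x (and the 0/0 case) are omitted, and the
#' median index is shifted by `K`, the number of pairwise slopes below -1
#' (the standard 1983 procedure, valid for positively correlated methods).
#' The intercept is the median of `y - slope * x`. The slope CI uses the
#' rank-based normal approximation.
#'
#' @param x,y paired measurements of the same analyte on two platforms
#'   (>= 3 complete pairs; `x` must not be constant).
#' @param conf confidence level for the slope CI (default 0.95).
#' @return object of class `pb_fit`: `slope`, `intercept`, `n_pairs`,
#'   `slope_ci`, `formula` (a human-readable rendering).
#' @export
passing_bablok <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs")
  if (length(unique(x)) == 1) stopf("x is constant; all pairwise slopes undefined")
  pairs <- utils::combn(n, 2)
  dx <- x[pairs[2, ]] - x[pairs[1, ]]
  dy <- y[pairs[2, ]] - y[pairs[1, ]]
  s <- ifelse(dx == 0, ifelse(dy == 0, NA_real_, sign(dy) * Inf), dy / dx)
  s <- s[!is.na(s) & s != -1]
  if (length(s) == 0) stopf("no valid pairwise slopes")
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  slope <- shifted_median(s, K)
  intercept <- stats::median(y - slope * x)
  # rank-based normal approximation CI on the slope order statistics
  w <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- max(1L, as.integer(round((N - w) / 2)))
  m2 <- min(N, N - m1 + 1L)
  ci <- c(s[min(N, m1 + K)], s[min(N, m2 + K)])
  structure(list(slope = slope, intercept = intercept, n_pairs = n,
                 slope_ci = ci,
                 formula = sprintf("y = %.6g * x + %.6g", slope, intercept)),
            class = "pb_fit")
}

shifted_median <- function(s, K) {
  N <- length(s)
  if (N %% 2 == 1) s[(N + 1) %/% 2 + K]
  else mean(s[c(N %/% 2 + K, N %/% 2 + 1 + K)])
}

#' @exportS3Method base::print
print.pb_fit <- function(x, ...) {
  cat(sprintf("Passing-Bablok fit (%d pairs): %s\n", x$n_pairs, x$formula))
  cat(sprintf("  slope 95%% CI: [%.4g, %.4g]\n", x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Apply a linear platform transformation
#'
#' @param values numeric vector on the source platform scale.
#' @param coeffs list or numeric with elements/names `slope`, `intercept`
#'   (e.g. a `pb_fit` or one row of [builtin_paper_transforms()]).
#' @return `slope * values + intercept`.
#' @export
apply_transform <- function(values, coeffs) {
  slope <- if (is.list(coeffs)) coeffs$slope else coeffs[["slope"]]
  intercept <- if (is.list(coeffs)) coeffs$intercept else coeffs[["intercept"]]
  if (!is.finite(slope) || !is.finite(intercept))
    stopf("transform coefficients must be finite")
  slope * values + intercept
}

#' Shipped Luminex-to-Innotest AD biomarker transformations
#'
#' The linear Passing-Bablok harmonization formulas for the three core AD
#' CSF biomarkers (Luminex xMAP values mapped onto the Innotest ELISA
#' scale), shipped as constants: the paired samples they were estimated from
#' are not publicly available, so they cannot be recomputed here.
#'
#' @return data.frame with columns `analyte`, `slope`, `intercept`:
#'   Abeta42 `4.65 x - 36.23`, tTau `5.28 x - 2.03`, pTau `1.88 x + 27.36`.
#' @export
builtin_paper_transforms <- function() {
  data.frame(
    analyte = c("Abeta42", "tTau", "pTau"),
    slope = c(4.65, 5.28, 1.88),
    intercept = c(-36.23, -2.03, 27.36),
    stringsAsFactors = FALSE
  )
}

#' Look up one shipped transformation
#'
#' @param analyte one of `"Abeta42"`, `"tTau"`, `"pTau"` (case-insensitive;
#'   `"Ab42"`/`"abeta42"` aliases accepted).
#' @return one-row data.frame with `analyte`, `slope`, `intercept`.
#' @export
get_transform <- function(analyte) {
  tab <- builtin_paper_transforms()
  key <- tolower(analyte)
  key <- c(ab42 = "abeta42", abeta42 = "abeta42", ttau = "ttau",
           ptau = "ptau")[key]
  hit <- match(key, tolower(tab$analyte))
  if (is.na(hit)) stopf("unknown analyte '%s' (available: %s)", analyte,
                        paste(tab$analyte, collapse = ", "))
  tab[hit, ]
}
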