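#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; percentage bookkeeping in this
#' package uses the conventional "round half up" rule instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5) * sign(x) / scale
}

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state. Values stay below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
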