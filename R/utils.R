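#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Trapezoid-rule integral
#'
#' @param x strictly increasing grid.
#' @param y function values at `x`.
#' @return Scalar integral approximation.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# trapezoid quadrature weights so that sum(w * y) == trapz(x, y)
trapz_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  c(d[1], d[-1] + d[-(n - 1)], d[n - 1]) / 2
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a scalar in [%s, %s], got: %s",
                 name, format(lower), format(upper),
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# deterministic per-stream seed derivation; keeps results invariant to
# adding later streams and stays inside 32-bit integer range
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 977 * as.numeric(stream)) %% 2147483629
}
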