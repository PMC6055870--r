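#' Normalized density on a grid
#'
#' The common currency of all Bayesian outputs: a scalar parameter's density
#' evaluated on a strictly increasing support grid, normalized so the
#' trapezoid integral equals 1.
#'
#' @param support strictly increasing numeric grid.
#' @param density non-negative values, same length as `support`.
#' @param normalize divide by the trapezoid integral (default). With
#'   `normalize = FALSE` the input must already integrate to 1 within 1e-6.
#' @return An object of class `grid_density`.
#' @export
grid_density <- function(support, density, normalize = TRUE) {
  stopifnot(is.numeric(support), is.numeric(density),
            length(support) == length(density), length(support) >= 3L)
  if (any(diff(support) <= 0)) {
    stop("`support` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("`density` must be finite and non-negative", call. = FALSE)
  }
  total <- trapz(support, density)
  if (total <= 0) stop("density integrates to zero", call. = FALSE)
  if (normalize) {
    density <- density / total
  } else if (abs(total - 1) > 1e-6) {
    stop("unnormalized input: trapezoid integral is ", format(total),
         call. = FALSE)
  }
  structure(list(support = support, density = density),
            class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  s <- summarize_posterior(x)
  cat(sprintf("<grid_density> %d points on [%.4g, %.4g]; mean %.4f, median %.4f\n",
              length(x$support), min(x$support), max(x$support),
              s$mean, s$median))
  invisible(x)
}

grid_cdf <- function(g) {
  n <- length(g$support)
  cdf <- c(0, cumsum((g$support[-1] - g$support[-n]) *
                       (g$density[-1] + g$density[-n]) / 2))
  pmin(cdf / cdf[n], 1)
}

grid_quantile <- function(g, p) {
  cdf <- grid_cdf(g)
  vapply(p, function(pp) {
    i <- findInterval(pp, cdf, rightmost.closed = TRUE)
    i <- max(1L, min(i, length(cdf) - 1L))
    span <- cdf[i + 1] - cdf[i]
    frac <- if (span > 0) (pp - cdf[i]) / span else 0.5
    g$support[i] + frac * (g$support[i + 1] - g$support[i])
  }, 0)
}

#' Summarize a grid density
#'
#' Mean and median by numeric integration, plus the central (equal-tailed)
#' credible interval obtained by inverse-CDF interpolation on the grid.
#'
#' @param g a [grid_density()] (must be normalized; a trapezoid integral off
#'   1 by more than 1e-6 is an error).
#' @param level credible level in (0, 1).
#' @return An object of class `posterior_summary` with fields `mean`,
#'   `median`, `cred_low`, `cred_high`, `level`.
#' @export
summarize_posterior <- function(g, level = 0.95) {
  stopifnot(inherits(g, "grid_density"))
  stopifnot_scalar(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  total <- trapz(g$support, g$density)
  if (abs(total - 1) > 1e-6) {
    stop("unnormalized input: trapezoid integral is ", format(total),
         call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- grid_quantile(g, c(alpha, 0.5, 1 - alpha))
  structure(list(mean = trapz(g$support, g$support * g$density),
                 median = q[2], cred_low = q[1], cred_high = q[3],
                 level = level),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> mean %.4f, median %.4f, %d%% CrI (%.4f, %.4f)\n",
              x$mean, x$median, round(100 * x$level), x$cred_low, x$cred_high))
  invisible(x)
}

#' Write / read a grid density as two-column CSV
#'
#' @param g a [grid_density()].
#' @param path file path; columns `support,density`.
#' @return `path` (writer, invisibly) or a `grid_density` (reader).
#' @export
write_grid_csv <- function(g, path) {
  stopifnot(inherits(g, "grid_density"))
  utils::write.csv(data.frame(support = g$support, density = g$density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  grid_density(df$support, df$density, normalize = TRUE)
}

# render a normal density on a grid spanning +/- 8.5 sd
normal_grid <- function(mean, sd, n = 801L) {
  x <- seq(mean - 8.5 * sd, mean + 8.5 * sd, length.out = n)
  grid_density(x, stats::dnorm(x, mean, sd))
}
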