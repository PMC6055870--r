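#' Heterogeneity priors on the between-study standard deviation
#'
#' Three prior families for the between-study heterogeneity of log odds
#' ratios are supported, covering the sensitivity grid used throughout the
#' package:
#' \describe{
#'   \item{half-normal on tau}{`half_normal_prior(scale)`, density
#'     `2/(s*sqrt(2*pi)) * exp(-tau^2/(2*s^2))` for `tau >= 0`.}
#'   \item{inverse-gamma on tau^2}{`inv_gamma_prior(scale, shape)`; the
#'     precision `1/tau^2` is Gamma(shape, rate = scale). Densities on the
#'     tau axis carry the Jacobian `2*tau`.}
#'   \item{point mass}{`point_mass_prior(tau0)`, known heterogeneity
#'     (`tau0 = 0` gives the common-effect model).}
#' }
#'
#' The inverse-gamma family is parameterized as scale-first (`IG(1/3, 1)`
#' means scale 1/3, shape 1); pass `parameter_order = "shape_scale"` to flip
#' the reading explicitly.
#'
#' @param scale positive scale parameter (half-normal scale `s`, or
#'   inverse-gamma scale `a`).
#' @param shape positive inverse-gamma shape `b`.
#' @param tau0 non-negative known heterogeneity value.
#' @param parameter_order how the two inverse-gamma arguments are read.
#' @return An object of class `het_prior`.
#' @examples
#' half_normal_prior(0.5)
#' inv_gamma_prior(1 / 1000, 1)
#' @export
half_normal_prior <- function(scale) {
  stopifnot_scalar(scale, "scale", lower = .Machine$double.xmin)
  structure(list(family = "half_normal", scale = scale),
            class = "het_prior")
}

#' @rdname half_normal_prior
#' @export
inv_gamma_prior <- function(scale, shape,
                            parameter_order = c("scale_shape", "shape_scale")) {
  parameter_order <- match.arg(parameter_order)
  if (parameter_order == "shape_scale") {
    tmp <- scale; scale <- shape; shape <- tmp
  }
  stopifnot_scalar(scale, "scale", lower = .Machine$double.xmin)
  stopifnot_scalar(shape, "shape", lower = .Machine$double.xmin)
  structure(list(family = "inverse_gamma", scale = scale, shape = shape),
            class = "het_prior")
}

#' @rdname half_normal_prior
#' @export
point_mass_prior <- function(tau0) {
  stopifnot_scalar(tau0, "tau0", lower = 0)
  structure(list(family = "point_mass", tau0 = tau0), class = "het_prior")
}

is_point_mass <- function(prior) {
  inherits(prior, "het_prior") && prior$family == "point_mass"
}

#' @export
format.het_prior <- function(x, ...) {
  switch(x$family,
         half_normal = sprintf("HN(%g)", x$scale),
         inverse_gamma = sprintf("IG(%s,%g)",
                                 ifelse(abs(x$scale - round(1 / x$scale)^-1) <
                                          1e-12 & x$scale < 1,
                                        paste0("1/", round(1 / x$scale)),
                                        format(x$scale)),
                                 x$shape),
         point_mass = sprintf("tau=%g", x$tau0))
}

#' @export
print.het_prior <- function(x, ...) {
  cat("<het_prior>", format(x), "\n")
  invisible(x)
}

#' Build a heterogeneity prior from a configuration list
#'
#' Accepts the plain-list syntax
#' `list(family = "half_normal"|"inverse_gamma"|"point", scale =, shape =,
#' on = "tau"|"tau2", value =)` as read from YAML/JSON configuration.
#'
#' @param config a named list.
#' @return A `het_prior`.
#' @export
het_prior_from_config <- function(config) {
  family <- match.arg(config$family, c("half_normal", "inverse_gamma", "point"))
  switch(family,
         half_normal = {
           if (!is.null(config$on) && config$on != "tau")
             stop("half-normal prior is specified on tau", call. = FALSE)
           half_normal_prior(config$scale)
         },
         inverse_gamma = {
           if (!is.null(config$on) && config$on != "tau2")
             stop("inverse-gamma prior is specified on tau2", call. = FALSE)
           inv_gamma_prior(config$scale, config$shape)
         },
         point = point_mass_prior(if (!is.null(config$value)) config$value
                                  else config$scale))
}

#' Prior density on the tau axis
#'
#' @param prior a continuous `het_prior` (density of a point mass is not
#'   defined and raises an error).
#' @param tau non-negative evaluation points.
#' @return Density values of tau (inverse-gamma priors on tau^2 include the
#'   change-of-variable Jacobian `2*tau`).
#' @export
prior_density <- function(prior, tau) {
  stopifnot(inherits(prior, "het_prior"))
  if (any(tau < 0)) stop("`tau` must be non-negative", call. = FALSE)
  switch(prior$family,
         half_normal = 2 * stats::dnorm(tau, 0, prior$scale),
         inverse_gamma = {
           # precision 1/tau^2 ~ Gamma(shape, rate = scale)
           t2 <- tau^2
           d <- ifelse(t2 > 0,
                       stats::dgamma(1 / t2, shape = prior$shape,
                                     rate = prior$scale) / t2^2,
                       0)
           d * 2 * tau
         },
         point_mass = stop("a point mass has no density on the tau axis",
                           call. = FALSE))
}

prior_cdf <- function(prior, tau) {
  switch(prior$family,
         half_normal = 2 * stats::pnorm(tau, 0, prior$scale) - 1,
         inverse_gamma = ifelse(tau > 0,
                                stats::pgamma(1 / tau^2, shape = prior$shape,
                                              rate = prior$scale,
                                              lower.tail = FALSE),
                                0),
         point_mass = as.numeric(tau >= prior$tau0))
}

prior_quantile <- function(prior, p) {
  switch(prior$family,
         half_normal = stats::qnorm((1 + p) / 2, 0, prior$scale),
         inverse_gamma = sqrt(1 / stats::qgamma(p, shape = prior$shape,
                                                rate = prior$scale,
                                                lower.tail = FALSE)),
         point_mass = rep(prior$tau0, length(p)))
}

#' Nominal heterogeneity and its trial-ratio translation
#'
#' Summarizes a heterogeneity prior by a representative between-study
#' variance and translates it into the expected ratio between the odds
#' ratios of two independent trials,
#' `or_ratio = exp(2 * 1.96 * sqrt(nominal_tau2))` (the ratio of the 97.5th
#' to the 2.5th percentile of trial-level ORs at that heterogeneity).
#' Conventions: half-normal uses the squared prior mean of tau,
#' `(E tau)^2 = scale^2 * 2/pi`; inverse-gamma uses `scale/shape` (the
#' reciprocal of the prior mean precision — the strict mean of tau^2 is
#' undefined at shape 1); a point mass uses `tau0^2`.
#'
#' @param prior a `het_prior`.
#' @return A list with `nominal_tau2` and `or_ratio`.
#' @examples
#' nominal_heterogeneity(half_normal_prior(0.5))
#' @export
nominal_heterogeneity <- function(prior) {
  stopifnot(inherits(prior, "het_prior"))
  nominal_tau2 <- switch(prior$family,
                         half_normal = prior$scale^2 * 2 / pi,
                         inverse_gamma = prior$scale / prior$shape,
                         point_mass = prior$tau0^2)
  list(nominal_tau2 = nominal_tau2,
       or_ratio = exp(2 * stats::qnorm(0.975) * sqrt(nominal_tau2)))
}

#' Draw heterogeneity values from a prior
#'
#' @param prior a `het_prior`.
#' @param n number of draws.
#' @param seed integer seed (draws are reproducible per seed).
#' @return Numeric vector of `n` non-negative tau draws.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "het_prior"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(prior$family,
         half_normal = abs(stats::rnorm(n, 0, prior$scale)),
         inverse_gamma = sqrt(1 / stats::rgamma(n, shape = prior$shape,
                                                rate = prior$scale)),
         point_mass = rep(prior$tau0, n))
}

#' The five-prior sensitivity grid
#'
#' The default battery of heterogeneity priors spanning no heterogeneity
#' (IG(1/1000,1), trial OR ratio about 1) to substantial heterogeneity
#' (HN(1), trial OR ratio above 20).
#'
#' @return Named list of `het_prior` objects:
#'   `IG(1/3,1)`, `IG(1/7,1)`, `IG(1/1000,1)`, `HN(1)`, `HN(0.5)`.
#' @export
default_het_priors <- function() {
  priors <- list(inv_gamma_prior(1 / 3, 1),
                 inv_gamma_prior(1 / 7, 1),
                 inv_gamma_prior(1 / 1000, 1),
                 half_normal_prior(1),
                 half_normal_prior(0.5))
  stats::setNames(priors, vapply(priors, format, ""))
}
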