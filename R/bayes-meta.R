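#' Normal prior specification
#'
#' @param mean prior mean.
#' @param scale prior variance (default reading) or standard deviation when
#'   `parameterization = "sd"`. `Inf` gives an improper flat prior.
#' @param parameterization `"variance"` (the convention used for the vague
#'   effect and control priors N(0,10) and N(0,4)) or `"sd"`.
#' @return An object of class `normal_prior` with fields `mean`, `var`.
#' @export
normal_prior <- function(mean = 0, scale = 10,
                         parameterization = c("variance", "sd")) {
  parameterization <- match.arg(parameterization)
  stopifnot_scalar(mean, "mean")
  stopifnot_scalar(scale, "scale", lower = .Machine$double.xmin,
                   allow_inf = TRUE)
  structure(list(mean = mean,
                 var = if (parameterization == "sd") scale^2 else scale,
                 parameterization = parameterization),
            class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  cat(sprintf("<normal_prior> N(mean = %g, VARIANCE = %g)%s\n", x$mean, x$var,
              if (x$parameterization == "sd") "  [entered on the SD scale]"
              else ""))
  invisible(x)
}

#' Configuration of the Bayesian engines
#'
#' @param effect_prior [normal_prior()] on the (overall) log odds ratio;
#'   default the vague N(0, 10) (variance parameterization).
#' @param control_prior [normal_prior()] on each study's control-arm logit
#'   event rate; default N(0, 4). Used only by the exact binomial-logit MCMC
#'   engine — the quadrature engine works on the normal approximation of the
#'   per-study log OR and does not model control rates.
#' @param het_prior a `het_prior` for random-effects analyses.
#' @param engine `"quadrature"` (deterministic, default) or `"mcmc"`.
#' @param level credible level of reported intervals.
#' @param n_tau,n_delta quadrature resolution: tau grid size (0 to the
#'   prior's 99.99% quantile, capped at 10) and log-OR grid size.
#' @param chains,iterations,burnin_frac,seed MCMC settings: number of chains
#'   (>= 2), iterations per chain, burn-in fraction, integer seed (mandatory
#'   for the MCMC engine).
#' @param interval `"central"` (equal-tailed, default) or `"hdi"`.
#' @return A list of class `bayes_config`.
#' @export
bayes_config <- function(effect_prior = normal_prior(0, 10),
                         control_prior = normal_prior(0, 4),
                         het_prior = NULL,
                         engine = c("quadrature", "mcmc"),
                         level = 0.95,
                         n_tau = 400L, n_delta = 800L,
                         chains = 4L, iterations = 10000L,
                         burnin_frac = 0.5, seed = NULL,
                         interval = c("central", "hdi")) {
  stopifnot(inherits(effect_prior, "normal_prior"),
            inherits(control_prior, "normal_prior"),
            is.null(het_prior) || inherits(het_prior, "het_prior"))
  stopifnot_scalar(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  structure(list(effect_prior = effect_prior, control_prior = control_prior,
                 het_prior = het_prior, engine = match.arg(engine),
                 level = level, n_tau = as.integer(n_tau),
                 n_delta = as.integer(n_delta), chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin_frac = burnin_frac, seed = seed,
                 interval = match.arg(interval)),
            class = "bayes_config")
}

# conjugate normal update of a common mean given observations with known
# variances; prior variance may be Inf (flat)
conjugate_normal <- function(d, v, prior) {
  prec0 <- if (is.finite(prior$var)) 1 / prior$var else 0
  m0 <- if (is.finite(prior$var)) prior$mean / prior$var else 0
  prec <- prec0 + sum(1 / v)
  list(mean = (m0 + sum(d / v)) / prec, var = 1 / prec)
}

# profile over a tau grid: log marginal likelihood of the observed log ORs
# (common mean integrated out analytically) plus the conditional posterior
# moments of the mean, at each grid point
tau_profile <- function(input, config, tau) {
  d <- input$estimate
  s2 <- input$se^2
  prior <- config$effect_prior
  k <- length(d)
  out <- vapply(tau, function(t) {
    v <- s2 + t^2
    m <- if (is.finite(prior$var)) prior$mean else d[1]
    pv <- if (is.finite(prior$var)) prior$var else v[1]
    logm <- 0
    start <- if (is.finite(prior$var)) 1L else 2L
    if (!is.finite(prior$var) && k >= 1L) {
      m <- d[1]; pv <- v[1]
    }
    if (start <= k) {
      for (i in start:k) {
        logm <- logm + stats::dnorm(d[i], m, sqrt(pv + v[i]), log = TRUE)
        w <- pv / (pv + v[i])
        m <- m + w * (d[i] - m)
        pv <- pv * v[i] / (pv + v[i])
      }
    }
    c(logm = logm, cond_mean = m, cond_var = pv)
  }, c(logm = 0, cond_mean = 0, cond_var = 0))
  data.frame(tau = tau, logm = out["logm", ],
             cond_mean = out["cond_mean", ], cond_var = out["cond_var", ])
}

default_tau_grid <- function(prior, n_tau) {
  upper <- min(prior_quantile(prior, 0.9999), 10)
  seq(0, upper, length.out = n_tau)
}

make_bayes_fit <- function(density, level, interval = "central",
                           tau_posterior = NULL, tau_summary = NULL) {
  s <- summarize_posterior(density, level = level)
  if (interval == "hdi") {
    h <- hdi_interval(density, level)
    s$cred_low <- h[1]; s$cred_high <- h[2]
  }
  structure(list(summary = s, density = density,
                 tau_posterior = tau_posterior, tau_summary = tau_summary),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("<bayes_fit>\n  effect: ")
  print(x$summary)
  if (!is.null(x$tau_summary)) {
    cat("  tau:    ")
    print(x$tau_summary)
  }
  invisible(x)
}

#' Highest-density interval of a grid density
#'
#' @param g a [grid_density()].
#' @param level credible level.
#' @return `c(low, high)`.
#' @export
hdi_interval <- function(g, level = 0.95) {
  cdf <- grid_cdf(g)
  probe <- seq(0, 1 - level, length.out = 512L)
  lows <- grid_quantile(g, probe)
  highs <- grid_quantile(g, probe + level)
  i <- which.min(highs - lows)
  c(lows[i], highs[i])
}

#' Bayesian fixed-effect meta-analysis (conjugate normal)
#'
#' Under the common-effect normal approximation the posterior is available
#' in closed form: precision `1/v0 + sum(w)`, mean the precision-weighted
#' combination of the prior mean and the study estimates. With a flat prior
#' (`var = Inf`) this reproduces the frequentist fixed-effect result exactly.
#'
#' @param input a [meta_input()].
#' @param config a [bayes_config()].
#' @return A `bayes_fit`: `summary` ([summarize_posterior()] output),
#'   `density` (the posterior as a [grid_density()]); the closed-form
#'   moments are attached as attributes `mean` and `var`.
#' @export
bayes_fixed_effect <- function(input, config = bayes_config()) {
  input <- meta_input(input)
  post <- conjugate_normal(input$estimate, input$se^2, config$effect_prior)
  g <- normal_grid(post$mean, sqrt(post$var), n = config$n_delta)
  fit <- make_bayes_fit(g, config$level, config$interval)
  attr(fit, "mean") <- post$mean
  attr(fit, "var") <- post$var
  fit
}

#' Marginal posterior of the heterogeneity parameter
#'
#' `p(tau | data)` proportional to `prior(tau) * m(data | tau)` where `m` is
#' the marginal likelihood of the observed log ORs after integrating the
#' common mean out analytically under its normal prior, evaluated on the tau
#' quadrature grid and normalized.
#'
#' @inheritParams bayes_fixed_effect
#' @return A [grid_density()] over tau, or (for a point-mass prior) a
#'   degenerate marker of class `point_mass_tau` with field `tau0`.
#' @export
marginal_tau_posterior <- function(input, config) {
  input <- meta_input(input)
  prior <- config$het_prior
  stopifnot(inherits(prior, "het_prior"))
  if (is_point_mass(prior)) {
    return(structure(list(tau0 = prior$tau0), class = "point_mass_tau"))
  }
  tau <- default_tau_grid(prior, config$n_tau)
  prof <- tau_profile(input, config, tau)
  logd <- log(prior_density(prior, tau)) + prof$logm
  logd[tau == 0 & !is.finite(logd)] <- -Inf
  dens <- exp(logd - max(logd[is.finite(logd)]))
  dens[!is.finite(dens)] <- 0
  grid_density(tau, dens)
}

#' Bayesian random-effects meta-analysis (quadrature engine)
#'
#' Normal-normal hierarchical model on the study log ORs: the posterior of
#' the overall effect is the tau-mixture of conjugate conditional normals,
#' `p(delta | data) = integral of p(delta | data, tau) p(tau | data) dtau`,
#' computed by trapezoid quadrature on the tau grid. A point-mass
#' heterogeneity prior gives the single conditional normal directly (and
#' with `tau0 = 0` reduces to [bayes_fixed_effect()]).
#'
#' @inheritParams bayes_fixed_effect
#' @return A `bayes_fit`; for continuous heterogeneity priors the fields
#'   `tau_posterior` ([grid_density()]) and `tau_summary` are filled in.
#' @export
bayes_random_effects <- function(input, config) {
  input <- meta_input(input)
  prior <- config$het_prior
  stopifnot(inherits(prior, "het_prior"))
  if (is_point_mass(prior)) {
    prof <- tau_profile(input, config, prior$tau0)
    g <- normal_grid(prof$cond_mean, sqrt(prof$cond_var), n = config$n_delta)
    fit <- make_bayes_fit(g, config$level, config$interval,
                          tau_posterior = structure(list(tau0 = prior$tau0),
                                                    class = "point_mass_tau"))
    attr(fit, "mean") <- prof$cond_mean
    attr(fit, "var") <- prof$cond_var
    return(fit)
  }
  tau <- default_tau_grid(prior, config$n_tau)
  prof <- tau_profile(input, config, tau)
  logw <- log(prior_density(prior, tau)) + prof$logm
  logw[!is.finite(logw)] <- -Inf
  w <- exp(logw - max(logw)) * trapz_weights(tau)
  w <- w / sum(w)
  tau_post <- grid_density(tau, exp(logw - max(logw)))
  sd_c <- sqrt(prof$cond_var)
  lo <- min(prof$cond_mean - 8 * sd_c)
  hi <- max(prof$cond_mean + 8 * sd_c)
  x <- seq(lo, hi, length.out = config$n_delta)
  dens <- as.vector(vapply(seq_along(tau), function(j)
    w[j] * stats::dnorm(x, prof$cond_mean[j], sd_c[j]),
    numeric(length(x))) %*% rep(1, length(tau)))
  g <- grid_density(x, dens)
  make_bayes_fit(g, config$level, config$interval,
                 tau_posterior = tau_post,
                 tau_summary = summarize_posterior(tau_post, config$level))
}
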