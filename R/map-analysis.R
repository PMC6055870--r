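#' Meta-analytic-predictive (MAP) priors from historical trials
#'
#' Step one of the two-step MAP procedure: the posterior-predictive
#' distribution of a new study's treatment effect given the historical
#' trials, used in step two ([map_update()]) as the prior for the new trial.
#'
#' `map_prior_fixed()` applies the common-effect assumption: the predictive
#' prior is `N(pooled estimate, pooled variance)` from the fixed-effect
#' meta-analysis of the historical set (with a single historical study,
#' `N(d_H, se_H^2)`).
#'
#' `map_prior_random()` allows between-study heterogeneity: the predictive
#' density is `p(d_new | hist) = integral of N(d_new | theta, tau^2) *
#' p(theta, tau | hist) dtheta dtau`, with the inner integral over the
#' hierarchical mean theta in closed form given tau and the outer tau
#' integral on the quadrature grid. A point-mass prior at `tau0` with a
#' single historical study gives the closed form `N(d_H, 2*tau0^2 + se_H^2)`
#' exactly (between-trial variability counted once for the historical and
#' once for the new trial). By default the hierarchical mean carries an
#' improper flat prior, under which these closed forms are exact; pass a
#' proper `effect_prior` in `config` to change that.
#'
#' @param historical a [meta_input()] of historical studies.
#' @param het_prior a `het_prior` on the between-study heterogeneity.
#' @param config a [bayes_config()]; defaults to a flat effect prior.
#' @return An object of class `map_prior`: either
#'   `representation = "normal"` with `mean` and `var`, or
#'   `representation = "grid"` with a [grid_density()] in `grid`;
#'   `provenance` records the historical labels and heterogeneity prior.
#' @export
map_prior_fixed <- function(historical) {
  historical <- meta_input(historical)
  fit <- fixed_effect_meta(historical)
  structure(list(representation = "normal",
                 mean = fit$estimate, var = fit$se^2, grid = NULL,
                 provenance = list(historical = historical$label,
                                   het_prior = "fixed-effect")),
            class = "map_prior")
}

map_config <- function() bayes_config(effect_prior = normal_prior(0, Inf))

#' @rdname map_prior_fixed
#' @export
map_prior_random <- function(historical, het_prior, config = map_config()) {
  historical <- meta_input(historical)
  stopifnot(inherits(het_prior, "het_prior"))
  prov <- list(historical = historical$label, het_prior = format(het_prior))
  if (is_point_mass(het_prior)) {
    prof <- tau_profile(historical, config, het_prior$tau0)
    return(structure(list(representation = "normal",
                          mean = prof$cond_mean,
                          var = prof$cond_var + het_prior$tau0^2,
                          grid = NULL, provenance = prov),
                     class = "map_prior"))
  }
  tau <- default_tau_grid(het_prior, config$n_tau)
  prof <- tau_profile(historical, config, tau)
  logw <- log(prior_density(het_prior, tau)) + prof$logm
  logw[!is.finite(logw)] <- -Inf
  w <- exp(logw - max(logw)) * trapz_weights(tau)
  w <- w / sum(w)
  pred_sd <- sqrt(prof$cond_var + tau^2)
  x <- seq(min(prof$cond_mean - 8 * pred_sd),
           max(prof$cond_mean + 8 * pred_sd),
           length.out = config$n_delta)
  dens <- rowSums(vapply(seq_along(tau), function(j)
    w[j] * stats::dnorm(x, prof$cond_mean[j], pred_sd[j]),
    numeric(length(x))))
  structure(list(representation = "grid", mean = NA_real_, var = NA_real_,
                 grid = grid_density(x, dens), provenance = prov),
            class = "map_prior")
}

#' @export
print.map_prior <- function(x, ...) {
  if (x$representation == "normal") {
    cat(sprintf("<map_prior> N(%.4f, %.4f^2) [%s; history: %s]\n",
                x$mean, sqrt(x$var), x$provenance$het_prior,
                paste(x$provenance$historical, collapse = ", ")))
  } else {
    s <- summarize_posterior(x$grid)
    cat(sprintf("<map_prior> grid: mean %.4f, sd ~%.4f [%s; history: %s]\n",
                s$mean, (s$cred_high - s$cred_low) / (2 * 1.959964),
                x$provenance$het_prior,
                paste(x$provenance$historical, collapse = ", ")))
  }
  invisible(x)
}

#' Update a MAP prior with the new trial
#'
#' Step two of the MAP procedure: the predictive prior is combined with the
#' normal likelihood of the new study's observed log OR. No heterogeneity
#' prior enters this step. Closed-normal priors use the conjugate update;
#' grid priors are multiplied pointwise by the likelihood and renormalized.
#'
#' @param prior a `map_prior`.
#' @param new_trial an [effect_estimate()] (or [two_arm_trial()], converted
#'   via [log_odds_ratio()]) for the new study.
#' @param level credible level.
#' @return A `bayes_fit` with the posterior summary and [grid_density()].
#' @export
map_update <- function(prior, new_trial, level = 0.95) {
  stopifnot(inherits(prior, "map_prior"))
  if (inherits(new_trial, "two_arm_trial")) {
    new_trial <- log_odds_ratio(new_trial)
  }
  stopifnot(inherits(new_trial, "effect_estimate"))
  if (prior$representation == "normal") {
    if (prior$var <= 0) stop("degenerate MAP prior (zero variance)",
                             call. = FALSE)
    post <- conjugate_normal(new_trial$log_or, new_trial$se^2,
                             list(mean = prior$mean, var = prior$var))
    g <- normal_grid(post$mean, sqrt(post$var))
    fit <- make_bayes_fit(g, level)
    attr(fit, "mean") <- post$mean
    attr(fit, "var") <- post$var
    return(fit)
  }
  g0 <- prior$grid
  dens <- g0$density * stats::dnorm(new_trial$log_or, g0$support, new_trial$se)
  make_bayes_fit(grid_density(g0$support, dens), level)
}

#' Joint (meta-analytic-combined) posterior of the new study's effect
#'
#' One-step counterpart of the sequential MAP procedure: a single Bayesian
#' random-effects analysis of historical and new trials together, reporting
#' the study-specific posterior of the new study's true effect. By the
#' meta-analytic-predictive construction the sequential and joint routes
#' target the same posterior, which makes this the correctness oracle for
#' [map_prior_random()] + [map_update()]. Given tau, the study-specific
#' posterior is the normal shrinkage combination
#' `w * d_new + (1 - w) * theta_post` with `w = tau^2/(tau^2 + se_new^2)`;
#' tau is integrated out over its posterior from all studies.
#'
#' @param all a [meta_input()] containing historical and new studies.
#' @param new_label the label of the new study within `all`.
#' @param het_prior a `het_prior`.
#' @param config a [bayes_config()]; defaults to a flat effect prior.
#' @return A `bayes_fit` for the new study's effect.
#' @export
mac_joint_posterior <- function(all, new_label, het_prior,
                                config = map_config()) {
  all <- meta_input(all)
  idx <- which(all$label == new_label)
  if (length(idx) != 1L) {
    stop("`new_label` must identify exactly one study; got '", new_label, "'",
         call. = FALSE)
  }
  stopifnot(inherits(het_prior, "het_prior"))
  d_new <- all$estimate[idx]
  v_new <- all$se[idx]^2

  cond_moments <- function(tau) {
    prof <- tau_profile(all, config, tau)
    wt <- tau^2 / (tau^2 + v_new)
    mean_i <- wt * d_new + (1 - wt) * prof$cond_mean
    var_i <- tau^2 * v_new / (tau^2 + v_new) + (1 - wt)^2 * prof$cond_var
    list(mean = mean_i, var = var_i, logm = prof$logm)
  }

  if (is_point_mass(het_prior)) {
    cm <- cond_moments(het_prior$tau0)
    g <- normal_grid(cm$mean, sqrt(cm$var), n = config$n_delta)
    fit <- make_bayes_fit(g, config$level)
    attr(fit, "mean") <- cm$mean
    attr(fit, "var") <- cm$var
    return(fit)
  }
  tau <- default_tau_grid(het_prior, config$n_tau)
  cm <- cond_moments(tau)
  logw <- log(prior_density(het_prior, tau)) + cm$logm
  logw[!is.finite(logw)] <- -Inf
  w <- exp(logw - max(logw)) * trapz_weights(tau)
  w <- w / sum(w)
  sd_c <- sqrt(cm$var)
  x <- seq(min(cm$mean - 8 * sd_c), max(cm$mean + 8 * sd_c),
           length.out = config$n_delta)
  dens <- rowSums(vapply(seq_along(tau), function(j)
    w[j] * stats::dnorm(x, cm$mean[j], sd_c[j]), numeric(length(x))))
  tau_post <- grid_density(tau, exp(logw - max(logw)))
  make_bayes_fit(grid_density(x, dens), config$level,
                 tau_posterior = tau_post,
                 tau_summary = summarize_posterior(tau_post, config$level))
}
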