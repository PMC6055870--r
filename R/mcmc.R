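#' Exact binomial-logit MCMC engine
#'
#' Metropolis-within-Gibbs sampler targeting the exact posterior of the
#' binomial-logit model: for each trial i, control events are
#' `Bin(n_Ci, inv_logit(mu_i))` and treatment events
#' `Bin(n_Ti, inv_logit(mu_i + delta_i))`, with vague normal priors
#' `mu_i ~ N(0, 4)` and `delta ~ N(0, 10)` (variance parameterization).
#' Under the fixed model all `delta_i = delta`; the random model adds the
#' hierarchical layer `delta_i ~ N(delta, tau^2)` with `tau` from the
#' configured heterogeneity prior (`delta | delta_i, tau` is updated by its
#' conjugate Gibbs step; all other parameters use adaptive Gaussian
#' random-walk Metropolis steps tuned to 20-40% acceptance during burn-in).
#' Zero-cell tables need no continuity correction: the binomial likelihood
#' is well defined for any event count.
#'
#' @param trials list of [two_arm_trial()] objects.
#' @param config a [bayes_config()]; `seed` must be set, `chains >= 2`.
#' @param model `"fixed"` or `"random"`; the random model requires
#'   `config$het_prior`.
#' @return An object of class `mcmc_fit`: `draws` (post-burn-in draws,
#'   iterations x parameters x chains), `summary` (posterior summary of the
#'   overall log OR `delta`), `rhat` and `ess` per parameter, `accept_rate`.
#'   Fails with a diagnostic error if any split-Rhat exceeds 1.05.
#' @export
mcmc_binomial_logit <- function(trials, config = bayes_config(),
                                model = c("fixed", "random")) {
  model <- match.arg(model)
  if (inherits(trials, "two_arm_trial")) trials <- list(trials)
  stopifnot(all(vapply(trials, inherits, TRUE, "two_arm_trial")))
  if (is.null(config$seed)) {
    stop("the MCMC engine requires `config$seed`", call. = FALSE)
  }
  if (config$chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  het <- config$het_prior
  if (model == "random" && is.null(het)) {
    stop("the random model requires `config$het_prior`", call. = FALSE)
  }
  fixed_tau <- model == "random" && is_point_mass(het)
  if (fixed_tau && het$tau0 == 0) {
    # degenerate hierarchy: all study effects coincide with the mean
    model <- "fixed"
    fixed_tau <- FALSE
  }

  xt <- vapply(trials, function(t) t$treatment$events, 0)
  nt <- vapply(trials, function(t) t$treatment$total, 0)
  xc <- vapply(trials, function(t) t$control$events, 0)
  nc <- vapply(trials, function(t) t$control$total, 0)
  k <- length(trials)
  mu_sd <- sqrt(config$control_prior$var)
  mu_mean <- config$control_prior$mean
  de_sd <- sqrt(config$effect_prior$var)
  de_mean <- config$effect_prior$mean

  par_names <- c(paste0("mu", seq_len(k)), "delta",
                 if (model == "random") paste0("delta", seq_len(k)),
                 if (model == "random" && !fixed_tau) "tau")
  n_iter <- config$iterations
  n_keep <- n_iter - floor(config$burnin_frac * n_iter)

  run_chain <- function(chain) {
    set.seed(derive_seed(config$seed, chain))
    mu <- logit(pmin(pmax((xc + 0.5) / (nc + 1), 0.02), 0.98)) +
      stats::rnorm(k, 0, 0.3)
    lor0 <- logit(pmin(pmax((xt + 0.5) / (nt + 1), 0.02), 0.98)) - mu
    delta <- mean(lor0) + stats::rnorm(1, 0, 0.3)
    di <- if (model == "random") lor0 else rep(delta, k)
    tau <- if (model == "random") {
      if (fixed_tau) het$tau0 else pmax(sample_prior(het, 1), 0.05)
    } else 0
    step <- rep(0.3, length(par_names))
    names(step) <- par_names
    acc <- win <- rep(0, length(par_names))
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))

    loglik_i <- function(i, mu_i, d_i) {
      stats::dbinom(xc[i], nc[i], inv_logit(mu_i), log = TRUE) +
        stats::dbinom(xt[i], nt[i], inv_logit(mu_i + d_i), log = TRUE)
    }

    kept <- 0L
    for (it in seq_len(n_iter)) {
      # control logits
      for (i in seq_len(k)) {
        prop <- mu[i] + stats::rnorm(1, 0, step[i])
        lr <- loglik_i(i, prop, di[i]) - loglik_i(i, mu[i], di[i]) +
          stats::dnorm(prop, mu_mean, mu_sd, log = TRUE) -
          stats::dnorm(mu[i], mu_mean, mu_sd, log = TRUE)
        win[i] <- win[i] + 1
        if (log(stats::runif(1)) < lr) { mu[i] <- prop; acc[i] <- acc[i] + 1 }
      }
      j <- k + 1L
      if (model == "fixed") {
        prop <- delta + stats::rnorm(1, 0, step[j])
        lr <- sum(vapply(seq_len(k), function(i)
          loglik_i(i, mu[i], prop) - loglik_i(i, mu[i], delta), 0)) +
          stats::dnorm(prop, de_mean, de_sd, log = TRUE) -
          stats::dnorm(delta, de_mean, de_sd, log = TRUE)
        win[j] <- win[j] + 1
        if (log(stats::runif(1)) < lr) { delta <- prop; acc[j] <- acc[j] + 1 }
        di <- rep(delta, k)
      } else {
        # conjugate Gibbs update of the hierarchical mean
        prec <- k / tau^2 + 1 / de_sd^2
        m <- (sum(di) / tau^2 + de_mean / de_sd^2) / prec
        delta <- stats::rnorm(1, m, sqrt(1 / prec))
        win[j] <- win[j] + 1; acc[j] <- acc[j] + 1
        # study-specific effects
        for (i in seq_len(k)) {
          jj <- k + 1L + i
          prop <- di[i] + stats::rnorm(1, 0, step[jj])
          lr <- loglik_i(i, mu[i], prop) - loglik_i(i, mu[i], di[i]) +
            stats::dnorm(prop, delta, tau, log = TRUE) -
            stats::dnorm(di[i], delta, tau, log = TRUE)
          win[jj] <- win[jj] + 1
          if (log(stats::runif(1)) < lr) { di[i] <- prop; acc[jj] <- acc[jj] + 1 }
        }
        if (!fixed_tau) {
          jj <- 2L * k + 2L
          prop <- tau + stats::rnorm(1, 0, step[jj])
          win[jj] <- win[jj] + 1
          if (prop > 0) {
            lr <- sum(stats::dnorm(di, delta, prop, log = TRUE)) -
              sum(stats::dnorm(di, delta, tau, log = TRUE)) +
              log(prior_density(het, prop)) - log(prior_density(het, tau))
            if (is.finite(lr) && log(stats::runif(1)) < lr) {
              tau <- prop; acc[jj] <- acc[jj] + 1
            }
          }
        }
      }
      # adapt proposals during burn-in
      if (it <= n_iter - n_keep && it %% 50L == 0L) {
        rate <- ifelse(win > 0, acc / win, 0.3)
        step <- step * ifelse(rate > 0.4, 1.15, ifelse(rate < 0.2, 0.85, 1))
        acc[] <- 0; win[] <- 0
      }
      if (it > n_iter - n_keep) {
        kept <- kept + 1L
        draws[kept, ] <- c(mu, delta,
                           if (model == "random") di,
                           if (model == "random" && !fixed_tau) tau)
      }
    }
    list(draws = draws, accept = ifelse(win > 0, acc / win, NA_real_))
  }

  chains <- lapply(seq_len(config$chains), run_chain)
  draws <- array(NA_real_, c(n_keep, length(par_names), config$chains),
                 dimnames = list(NULL, par_names, NULL))
  for (c in seq_len(config$chains)) draws[, , c] <- chains[[c]]$draws

  rhat <- apply(draws, 2, function(m) split_rhat(m))
  ess <- apply(draws, 2, function(m) ess_basic(m))
  if (any(rhat > 1.05, na.rm = TRUE)) {
    bad <- names(rhat)[which(rhat > 1.05)]
    stop("MCMC did not converge: split-Rhat > 1.05 for ",
         paste0(bad, " (", sprintf("%.3f", rhat[bad]), ")", collapse = ", "),
         call. = FALSE)
  }
  dd <- as.vector(draws[, "delta", ])
  qs <- stats::quantile(dd, c((1 - config$level) / 2, 0.5,
                              (1 + config$level) / 2), names = FALSE)
  summary <- structure(list(mean = mean(dd), median = qs[2],
                            cred_low = qs[1], cred_high = qs[3],
                            level = config$level),
                       class = "posterior_summary")
  structure(list(draws = draws, summary = summary, rhat = rhat, ess = ess,
                 model = model, parameters = par_names,
                 mcse_delta = stats::sd(dd) / sqrt(max(ess["delta"], 1)),
                 accept_rate = rowMeans(vapply(chains, `[[`,
                                               numeric(length(par_names)),
                                               "accept"), na.rm = TRUE)),
            class = "mcmc_fit")
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf("<mcmc_fit> %s binomial-logit model, %d chains x %d kept draws\n",
              x$model, dim(x$draws)[3], dim(x$draws)[1]))
  cat("  delta: ")
  print(x$summary)
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n",
              max(x$rhat), min(x$ess)))
  invisible(x)
}

# split-Rhat (Gelman-Rubin on split chains)
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# effective sample size via Geyer's initial positive sequence, pooled chains
ess_basic <- function(mat) {
  m <- ncol(mat)
  n <- nrow(mat)
  rho_sum <- 0
  for (c in seq_len(m)) {
    x <- mat[, c]
    if (stats::sd(x) == 0) next
    ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (t in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[t] + ac[t + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  rho <- rho_sum / m
  m * n / (1 + 2 * rho)
}
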