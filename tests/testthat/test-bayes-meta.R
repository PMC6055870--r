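test_that("grid-density summaries recover known distributions", {
  g <- mapmeta:::normal_grid(0, 1, n = 2001)
  s <- summarize_posterior(g, 0.95)
  expect_equal(s$median, 0, tolerance = 1e-4)
  expect_equal(s$mean, 0, tolerance = 1e-6)
  expect_equal(c(s$cred_low, s$cred_high), c(-1.959964, 1.959964),
               tolerance = 5e-3)
  g2 <- mapmeta:::normal_grid(1, 2, n = 2001)
  expect_equal(summarize_posterior(g2)$mean, 1, tolerance = 1e-3)

  # bimodal mixture: oracle interval from the closed-form mixture CDF
  x <- seq(-2, 2, length.out = 4001)
  dens <- 0.5 * dnorm(x, -1, 0.1) + 0.5 * dnorm(x, 1, 0.1)
  gm <- grid_density(x, dens)
  sm <- summarize_posterior(gm, 0.95)
  mix_cdf <- function(q) 0.5 * pnorm(q, -1, 0.1) + 0.5 * pnorm(q, 1, 0.1)
  oracle_q <- function(p) uniroot(function(q) mix_cdf(q) - p, c(-2, 2),
                                  tol = 1e-10)$root
  expect_gt(sm$median, -0.2); expect_lt(sm$median, 0.2)
  expect_equal(sm$cred_low, oracle_q(0.025), tolerance = 5e-3)
  expect_equal(sm$cred_high, oracle_q(0.975), tolerance = 5e-3)

  expect_error(grid_density(c(1, 1, 2), c(1, 1, 1)), "increasing")
  expect_error(grid_density(x, 2 * dens, normalize = FALSE), "unnormalized")
})

test_that("conjugate fixed-effect posterior matches hand-worked precision weighting", {
  single <- meta_input(data.frame(label = "s", estimate = 0.5, se = 0.2))
  fit <- bayes_fixed_effect(single, bayes_config(effect_prior = normal_prior(0, 0.04)))
  expect_equal(attr(fit, "mean"), 0.25, tolerance = 1e-12)
  expect_equal(attr(fit, "var"), 0.02, tolerance = 1e-12)
  expect_equal(fit$summary$mean, 0.25, tolerance = 1e-4)

  adult_fit <- bayes_fixed_effect(adult_input)
  expect_equal(adult_fit$summary$mean, -0.035, tolerance = 0.01)
  expect_lt(abs(adult_fit$summary$cred_low - (-0.28)), 0.02)
  expect_lt(abs(adult_fit$summary$cred_high - 0.21), 0.02)

  # flat-prior limit reproduces the frequentist result exactly
  flat <- bayes_fixed_effect(adult_input,
                             bayes_config(effect_prior = normal_prior(0, Inf)))
  fe <- fixed_effect_meta(adult_input)
  expect_equal(attr(flat, "mean"), fe$estimate, tolerance = 1e-12)
  expect_equal(attr(flat, "var"), fe$se^2, tolerance = 1e-12)
})

test_that("two studies barely update a heterogeneity prior", {
  cfg <- bayes_config(het_prior = half_normal_prior(1))
  post <- marginal_tau_posterior(bond_opera_input, cfg)
  p_post <- grid_cdf_at(post, 0.1)
  p_prior <- mapmeta:::prior_cdf(half_normal_prior(1), 0.1)
  expect_lt(abs(p_post - p_prior), 0.15)
})

test_that("point-mass heterogeneity returns a degenerate marker and reduces to fixed effect", {
  cfg <- bayes_config(het_prior = point_mass_prior(0.4))
  marker <- marginal_tau_posterior(adult_input, cfg)
  expect_s3_class(marker, "point_mass_tau")
  expect_identical(marker$tau0, 0.4)
  cfg0 <- bayes_config(het_prior = point_mass_prior(0))
  re <- bayes_random_effects(input_s1, cfg0)
  fe <- bayes_fixed_effect(input_s1)
  expect_lt(abs(re$summary$mean - fe$summary$mean), 1e-6)
  expect_lt(abs(re$summary$cred_low - fe$summary$cred_low), 1e-6)
})

test_that("the heterogeneity posterior concentrates near truth in a 50-study meta-analysis", {
  set.seed(401)
  k <- 50; tau_true <- 0.5
  d <- rnorm(k, 0.2 + rnorm(k, 0, tau_true), 0.15)
  inp <- meta_input(data.frame(label = paste0("s", 1:k),
                               estimate = d, se = rep(0.15, k)))
  cfg <- bayes_config(het_prior = half_normal_prior(1))
  post <- marginal_tau_posterior(inp, cfg)
  med <- summarize_posterior(post)$median
  expect_gt(med, 0.35); expect_lt(med, 0.65)
})

test_that("credible intervals widen with assumed heterogeneity on the homogeneous battery", {
  widths <- vapply(c("IG(1/1000,1)", "HN(0.5)", "HN(1)"), function(nm) {
    cfg <- bayes_config(het_prior = default_het_priors()[[nm]])
    s <- bayes_random_effects(input_s1, cfg)$summary
    s$cred_high - s$cred_low
  }, 0)
  expect_true(all(diff(widths) > 0))
  ig_widths <- vapply(c("IG(1/1000,1)", "IG(1/7,1)", "IG(1/3,1)"), function(nm) {
    cfg <- bayes_config(het_prior = default_het_priors()[[nm]])
    s <- bayes_random_effects(input_s1, cfg)$summary
    s$cred_high - s$cred_low
  }, 0)
  expect_true(all(diff(ig_widths) > 0))
})

test_that("two identical studies give a posterior centred on the common estimate", {
  est <- log_odds_ratio(fx$vitko)
  dup <- meta_input(data.frame(label = c("a", "b"),
                               estimate = rep(est$log_or, 2),
                               se = rep(est$se, 2)))
  # under a flat effect prior the tau-mixture is symmetric about the common
  # estimate; a proper vague prior adds only a small shrinkage toward zero
  for (prior in list(half_normal_prior(1), inv_gamma_prior(1 / 3, 1))) {
    cfg <- bayes_config(effect_prior = normal_prior(0, Inf),
                        het_prior = prior)
    fit <- bayes_random_effects(dup, cfg)
    expect_lt(abs(fit$summary$mean - est$log_or), 1e-3)
    vague <- bayes_random_effects(dup, bayes_config(het_prior = prior))
    expect_lt(abs(vague$summary$mean - est$log_or), 5e-3)
  }
})

test_that("doubling the grid resolution leaves posterior means essentially unchanged", {
  cfg1 <- bayes_config(het_prior = half_normal_prior(0.5))
  cfg2 <- bayes_config(het_prior = half_normal_prior(0.5),
                       n_tau = 800L, n_delta = 1600L)
  f1 <- bayes_random_effects(input_s2, cfg1)
  f2 <- bayes_random_effects(input_s2, cfg2)
  expect_lt(abs(f1$summary$mean - f2$summary$mean), 1e-4)
  b1 <- bayes_fixed_effect(adult_input, cfg1)
  b2 <- bayes_fixed_effect(adult_input, cfg2)
  expect_lt(abs(b1$summary$mean - b2$summary$mean), 1e-4)
})

test_that("widening the effect prior moves the posterior mean monotonically toward the frequentist pool", {
  fe <- fixed_effect_meta(bond_opera_input)$estimate
  means <- vapply(c(0.1, 1, 10, 100), function(v) {
    attr(bayes_fixed_effect(bond_opera_input,
                            bayes_config(effect_prior = normal_prior(0, v))),
         "mean")
  }, 0)
  gaps <- abs(means - fe)
  expect_true(all(diff(gaps) < 0))
})

test_that("posterior ranks are uniform under the random-effects model (simulation-based calibration)", {
  set.seed(707)
  n_rep <- 200
  k <- 4
  se_i <- c(0.25, 0.2, 0.3, 0.4)
  prior <- half_normal_prior(0.5)
  cfg <- quick_config(het_prior = prior)
  pit <- vapply(seq_len(n_rep), function(r) {
    delta <- rnorm(1, 0, sqrt(10))
    tau <- abs(rnorm(1, 0, 0.5))
    d_i <- rnorm(k, rnorm(k, delta, tau), se_i)
    inp <- meta_input(data.frame(label = paste0("s", 1:k),
                                 estimate = d_i, se = se_i))
    grid_cdf_at(bayes_random_effects(inp, cfg)$density, delta)
  }, 0)
  counts <- table(cut(pit, breaks = seq(0, 1, by = 0.1),
                      include.lowest = TRUE))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("HDI intervals are available and no wider than the central interval", {
  cfg <- bayes_config(het_prior = half_normal_prior(1), interval = "hdi")
  hdi_fit <- bayes_random_effects(input_s2, cfg)
  cen_fit <- bayes_random_effects(input_s2,
                                  bayes_config(het_prior = half_normal_prior(1)))
  expect_lte(hdi_fit$summary$cred_high - hdi_fit$summary$cred_low,
             cen_fit$summary$cred_high - cen_fit$summary$cred_low + 1e-6)
})
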