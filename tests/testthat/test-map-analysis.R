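test_that("fixed-effect MAP priors are the pooled normal", {
  pr <- map_prior_fixed(adult_input)
  expect_identical(pr$representation, "normal")
  expect_equal(pr$mean, fixed_effect_meta(adult_input)$estimate,
               tolerance = 1e-12)
  expect_equal(round(pr$mean, 3), -0.035)
  expect_equal(round(sqrt(pr$var), 4), 0.1238)
  single <- map_prior_fixed(meta_input(list(fx$bond)))
  est <- log_odds_ratio(fx$bond)
  expect_equal(single$mean, est$log_or, tolerance = 1e-12)
  expect_equal(single$var, est$se^2, tolerance = 1e-12)
  expect_equal(single$mean, 0.741, tolerance = 1e-3)
  expect_equal(sqrt(single$var), 0.206, tolerance = 1e-3)
})

test_that("random-effects MAP priors obey the known-tau closed form", {
  # point mass at 0 reduces to the fixed-effect MAP prior
  pr0 <- map_prior_random(meta_input(list(fx$bond)), point_mass_prior(0))
  fixed <- map_prior_fixed(meta_input(list(fx$bond)))
  expect_equal(pr0$mean, fixed$mean, tolerance = 1e-12)
  expect_equal(pr0$var, fixed$var, tolerance = 1e-12)
  # single historical study, known tau: predictive variance 2*tau^2 + se^2
  hist <- meta_input(data.frame(label = "h", estimate = 0.5, se = 0.2))
  pr <- map_prior_random(hist, point_mass_prior(0.3))
  expect_equal(pr$mean, 0.5, tolerance = 1e-12)
  expect_equal(pr$var, 2 * 0.09 + 0.04, tolerance = 1e-12)
})

test_that("a wider heterogeneity prior gives a wider predictive prior", {
  sd_of <- function(prior) {
    pr <- map_prior_random(adult_input, prior)
    s <- summarize_posterior(pr$grid)
    sqrt(mapmeta:::trapz(pr$grid$support,
                         (pr$grid$support - s$mean)^2 * pr$grid$density))
  }
  expect_gt(sd_of(half_normal_prior(1)), sd_of(inv_gamma_prior(1 / 1000, 1)))
})

test_that("updating with the new trial follows conjugate precision weighting", {
  # Bond as history, Opera as the new study: near-equal weighting
  prior <- map_prior_fixed(meta_input(list(fx$bond)))
  opera <- log_odds_ratio(fx$opera)
  post <- map_update(prior, opera)
  pooled <- fixed_effect_meta(bond_opera_input)
  expect_equal(attr(post, "mean"), pooled$estimate, tolerance = 1e-10)
  expect_equal(attr(post, "mean"), 0.45, tolerance = 0.01)
  w_hist <- (1 / prior$var) / (1 / prior$var + 1 / opera$se^2)
  expect_gt(w_hist, 0.45); expect_lt(w_hist, 0.55)

  # adult MAP prior + homogeneous paediatric scenario
  s1 <- log_odds_ratio(fx$scenario1)
  adult_prior <- map_prior_random(adult_input, point_mass_prior(0))
  post2 <- map_update(adult_prior, s1)
  expect_gt(attr(post2, "mean"), -0.035)
  expect_lt(attr(post2, "mean"), 0)
  expect_lt(abs(attr(post2, "mean") - (-0.035)),
            abs(attr(post2, "mean") - 0))

  # flat-prior limit: posterior equals the new study's own estimate
  flat <- structure(list(representation = "normal", mean = 0, var = Inf,
                         grid = NULL, provenance = list()),
                    class = "map_prior")
  post3 <- map_update(flat, s1)
  expect_equal(attr(post3, "mean"), s1$log_or, tolerance = 1e-10)
  expect_equal(sqrt(attr(post3, "var")), s1$se, tolerance = 1e-10)

  bad <- flat; bad$var <- 0
  expect_error(map_update(bad, s1), "degenerate")
})

test_that("sequential MAP equals the joint study-specific posterior on every fixture x prior", {
  fixture_sets <- list(
    list(hist = list(fx$bond), new = fx$opera, all = bond_opera_input,
         label = "Opera"),
    list(hist = adult_trials, new = fx$scenario1, all = input_s1,
         label = "Scenario 1"),
    list(hist = adult_trials, new = fx$scenario2, all = input_s2,
         label = "Scenario 2")
  )
  priors <- c(default_het_priors(), list("tau=0.3" = point_mass_prior(0.3)))
  for (fs in fixture_sets) {
    hist_input <- meta_input(fs$hist)
    new_est <- log_odds_ratio(fs$new)
    for (nm in names(priors)) {
      seq_post <- map_update(map_prior_random(hist_input, priors[[nm]]),
                             new_est)
      joint <- mac_joint_posterior(fs$all, fs$label, priors[[nm]])
      expect_lt(abs(seq_post$summary$mean - joint$summary$mean), 5e-3)
    }
  }
})

test_that("known-tau grid pipeline matches the closed form to high accuracy", {
  hist <- meta_input(data.frame(label = "h", estimate = 0.5, se = 0.2))
  new_est <- effect_estimate(0.1, 0.35, label = "new")
  for (tau0 in c(0.15, 0.3, 0.6)) {
    closed <- map_update(map_prior_random(hist, point_mass_prior(tau0)),
                         new_est)
    # same model via an explicit fine grid prior
    m <- 0.5; v <- 0.04 + 2 * tau0^2
    x <- seq(m - 9 * sqrt(v), m + 9 * sqrt(v), length.out = 4001)
    grid_pr <- structure(list(representation = "grid", mean = NA, var = NA,
                              grid = grid_density(x, dnorm(x, m, sqrt(v))),
                              provenance = list()),
                         class = "map_prior")
    gridded <- map_update(grid_pr, new_est)
    expect_lt(abs(closed$summary$mean - gridded$summary$mean), 1e-4)
    sd_c <- (closed$summary$cred_high - closed$summary$cred_low) / 2
    sd_g <- (gridded$summary$cred_high - gridded$summary$cred_low) / 2
    expect_lt(abs(sd_c - sd_g), 1e-4)
  }
})

test_that("borrowing weakens as assumed heterogeneity grows", {
  new_est <- log_odds_ratio(fx$scenario2)
  dist_for <- function(prior) {
    post <- map_update(map_prior_random(adult_input, prior), new_est)
    abs(post$summary$mean - new_est$log_or)
  }
  ig_chain <- vapply(list(inv_gamma_prior(1 / 1000, 1),
                          inv_gamma_prior(1 / 7, 1),
                          inv_gamma_prior(1 / 3, 1)), dist_for, 0)
  expect_true(all(diff(ig_chain) < 0))
  hn_chain <- vapply(list(half_normal_prior(0.5), half_normal_prior(1)),
                     dist_for, 0)
  expect_true(all(diff(hn_chain) < 0))
  pm_chain <- vapply(list(point_mass_prior(0), point_mass_prior(0.3),
                          point_mass_prior(0.8)), dist_for, 0)
  expect_true(all(diff(pm_chain) < 0))
})

test_that("the joint posterior interpolates between pooling and no borrowing", {
  pooled <- fixed_effect_meta(input_s2)
  joint0 <- mac_joint_posterior(input_s2, "Scenario 2", point_mass_prior(0))
  expect_equal(attr(joint0, "mean"), pooled$estimate, tolerance = 1e-10)
  s2 <- log_odds_ratio(fx$scenario2)
  joint_big <- mac_joint_posterior(input_s2, "Scenario 2",
                                   point_mass_prior(10))
  expect_lt(abs(joint_big$summary$mean - s2$log_or), 0.05)
  expect_error(mac_joint_posterior(input_s2, "nope", point_mass_prior(0)),
               "new_label")
})
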