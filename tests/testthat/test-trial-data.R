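test_that("log odds ratios and Woolf standard errors match direct cell arithmetic", {
  cases <- list(
    list(trial = fx$bond, a = 93, nt = 219, c = 57, nc = 219),
    list(trial = fx$opera, a = 68, nt = 202, c = 62, nc = 203),
    list(trial = fx$lorber, a = 48, nt = 193, c = 54, nc = 196),
    list(trial = fx$scenario2, a = 22, nt = 53, c = 16, nc = 53)
  )
  for (cs in cases) {
    est <- log_odds_ratio(cs$trial)
    orc <- oracle_log_or(cs$a, cs$nt, cs$c, cs$nc)
    expect_equal(est$log_or, orc$est, tolerance = 1e-12)
    expect_equal(est$se, orc$se, tolerance = 1e-12)
  }
  expect_identical(log_odds_ratio(fx$scenario1)$log_or, 0)
  expect_equal(round(log_odds_ratio(fx$bond)$log_or, 2), 0.74)
  expect_equal(round(log_odds_ratio(fx$lorber)$log_or, 4), -0.1387)
  expect_equal(round(log_odds_ratio(fx$lorber)$se, 4), 0.2308)
})

test_that("Wald intervals are symmetric and reproduce the printed scenario bounds", {
  s1 <- log_odds_ratio(fx$scenario1)
  expect_equal(round(wald_interval(s1, 0.95), 2),
               c(low = -0.83, high = 0.83))
  opera <- log_odds_ratio(fx$opera)
  expect_equal(round(wald_interval(opera, 0.95), 3),
               c(low = -0.274, high = 0.561))
  for (lev in c(0.5, 0.8, 0.95, 0.99)) {
    ci <- wald_interval(opera, lev)
    expect_equal(mean(ci), opera$log_or)
  }
  expect_error(wald_interval(opera, 1.2), "level")
})

test_that("p-value sidedness: Opera matches the one-sided report, Table-2 studies the two-sided one", {
  expect_lt(abs(log_odds_ratio(fx$opera, p_sided = "one_sided")$p_value -
                  0.252), 5e-3)
  expect_equal(log_odds_ratio(fx$vitko)$p_value, 0.793, tolerance = 5e-3)
  expect_equal(log_odds_ratio(fx$lorber)$p_value, 0.548, tolerance = 5e-3)
  expect_lt(log_odds_ratio(fx$bond)$p_value, 0.001)
})

test_that("noninferiority margin translation reproduces the 0.43 log OR anchor", {
  expect_equal(margin_to_log_or(0.311, 0.10), 0.436, tolerance = 1e-3)
  expect_equal(exp(margin_to_log_or(0.315, 0.10)), 1.543, tolerance = 1e-3)
  for (p in c(0.1, 0.3, 0.7)) expect_identical(margin_to_log_or(p, 0), 0)
  expect_error(margin_to_log_or(0.95, 0.10), "must lie")
  expect_error(margin_to_log_or(1.2, 0.1))
})

test_that("swapping arms negates the log OR and preserves the standard error", {
  for (tr in fx) {
    swapped <- two_arm_trial(tr$label, tr$control$events, tr$control$total,
                             tr$treatment$events, tr$treatment$total)
    a <- log_odds_ratio(tr); b <- log_odds_ratio(swapped)
    expect_equal(b$log_or, -a$log_or, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }
})

test_that("scaling all cells by k shrinks the standard error like 1/sqrt(k)", {
  base <- log_odds_ratio(fx$bond)
  for (k in c(2, 10)) {
    scaled <- two_arm_trial("scaled", 93 * k, 219 * k, 57 * k, 219 * k)
    est <- log_odds_ratio(scaled)
    expect_equal(est$log_or, base$log_or, tolerance = 1e-12)
    expect_equal(est$se, base$se / sqrt(k), tolerance = 1e-12)
  }
})

test_that("degenerate tables error without the continuity correction and shift with it", {
  zt <- two_arm_trial("zero", 0, 20, 5, 20)
  expect_error(log_odds_ratio(zt), "treatment events")
  corrected <- log_odds_ratio(zt, correction = TRUE)
  expect_equal(corrected$log_or,
               log((0.5 / 20.5) / (5.5 / 15.5)), tolerance = 1e-12)
  # correction leaves clean tables untouched
  expect_equal(log_odds_ratio(fx$bond, correction = TRUE)$log_or,
               log_odds_ratio(fx$bond)$log_or)
  expect_error(two_arm_trial("bad", 1, 0, 1, 5), "total 0")
  expect_error(two_arm_trial("bad", 6, 5, 1, 5), "events <= total")
})

test_that("95% Wald intervals achieve nominal coverage under the null", {
  set.seed(20240917)
  n_rep <- 2500
  xt <- rbinom(n_rep, 200, 0.3)
  xc <- rbinom(n_rep, 200, 0.3)
  covered <- vapply(seq_len(n_rep), function(i) {
    est <- log_odds_ratio(two_arm_trial("r", xt[i], 200, xc[i], 200))
    est$ci_low <= 0 && 0 <= est$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("trial CSV and JSON round-trips preserve counts, labels and roles", {
  trials <- fx[c("bond", "scenario1")]
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_trials_csv(trials, csv)
  expect_identical(readLines(csv)[1],
                   "label,treatment_events,treatment_total,control_events,control_total,role")
  back <- read_trials_csv(csv)
  expect_identical(unname(lapply(back, unclass)),
                   unname(lapply(trials, unclass)))
  write_trials_json(trials, json)
  back2 <- read_trials_json(json)
  expect_identical(unname(lapply(back2, unclass)),
                   unname(lapply(trials, unclass)))
  unlink(c(csv, json))
})
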