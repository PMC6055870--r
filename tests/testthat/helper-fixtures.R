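# shared fixtures and small oracles used across test files

fx <- trial_fixtures()
adult_trials <- fx[c("vitko", "lorber", "tedesco")]
adult_input <- meta_input(adult_trials)
input_s1 <- meta_input(c(adult_trials, fx["scenario1"]))
input_s2 <- meta_input(c(adult_trials, fx["scenario2"]))
bond_opera_input <- meta_input(fx[c("bond", "opera")])

# independent log-OR oracle: direct cell arithmetic on the 2x2 table
oracle_log_or <- function(a, nt, c, nc) {
  list(est = log((a / (nt - a)) / (c / (nc - c))),
       se = sqrt(1 / a + 1 / (nt - a) + 1 / c + 1 / (nc - c)))
}

# two-point weighted-mean oracle for n = 2 meta-analysis
oracle_two_point <- function(d1, v1, d2, v2) {
  w <- c(1 / v1, 1 / v2)
  list(est = sum(w * c(d1, d2)) / sum(w), var = 1 / sum(w))
}

# posterior CDF of a grid density at a point (linear interpolation)
grid_cdf_at <- function(g, x) {
  cdf <- mapmeta:::grid_cdf(g)
  stats::approx(g$support, cdf, xout = x, rule = 2)$y
}

quick_config <- function(...) {
  bayes_config(n_tau = 200L, n_delta = 400L, ...)
}
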