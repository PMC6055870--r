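#!/usr/bin/env Rscript
# Paediatric extrapolation, heterogeneous case: the paediatric outcome
# (Scenario 2, log OR 0.50) sits just past the 0.43 noninferiority margin
# while the adult pool is at -0.035. How much the conclusion borrows from
# the adults is controlled entirely by the heterogeneity prior.

library(mapmeta)

dir.create("results", showWarnings = FALSE)
fx <- trial_fixtures()
adults <- fx[c("vitko", "lorber", "tedesco")]
adult_input <- meta_input(adults)

rows <- run_comparison(adults, fx$scenario2)
write_analysis_rows(rows, "results/heterogeneous_battery.csv")
print(as.data.frame(rows), digits = 3, row.names = FALSE)

q <- cochran_q(meta_input(c(adults, fx["scenario2"])))
cat(sprintf("\nCochran Q = %.2f (p = %.3f): the heterogeneity test cannot detect\n",
            q$q, q$p))
cat("the adult/paediatric discrepancy at this paediatric sample size.\n\n")

# prior sensitivity: how far each MAP posterior sits from the paediatric
# estimate (more assumed heterogeneity -> less borrowing from adults)
s2 <- log_odds_ratio(fx$scenario2)
priors <- default_het_priors()
sens <- do.call(rbind, lapply(names(priors), function(nm) {
  fit <- map_update(map_prior_random(adult_input, priors[[nm]]), s2)
  data.frame(prior = nm,
             nominal_tau2 = round(nominal_heterogeneity(priors[[nm]])$nominal_tau2, 3),
             map_median = round(fit$summary$median, 3),
             map_mean = round(fit$summary$mean, 3),
             dist_to_paediatric = round(abs(fit$summary$mean - s2$log_or), 3),
             ci_high = round(fit$summary$cred_high, 3),
             noninferior = fit$summary$cred_high < 0.43)
}))
write.csv(sens, "results/prior_sensitivity.csv", row.names = FALSE)
cat("MAP prior sensitivity (Scenario 2):\n")
print(sens, row.names = FALSE)
cat("\nBorrowing falls with assumed heterogeneity within each prior family;\n")
cat("the skewed half-normal posteriors give the adult data more weight than\n")
cat("inverse-gamma priors of similar nominal heterogeneity. Noninferiority\n")
cat("is concluded only when (near-)zero heterogeneity is assumed a priori.\n")
cat("Wrote results/heterogeneous_battery.csv and results/prior_sensitivity.csv\n")
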