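#!/usr/bin/env Rscript
# Paediatric extrapolation, homogeneous case: three adult transplant trials
# plus a paediatric outcome identical in rate to the adult pool
# (Scenario 1). Events are treatment failures, margin 0.43 log OR.

library(mapmeta)

dir.create("results", showWarnings = FALSE)
fx <- trial_fixtures()
adults <- fx[c("vitko", "lorber", "tedesco")]

rows <- run_comparison(adults, fx$scenario1)
write_analysis_rows(rows, "results/homogeneous_battery.csv")
print(as.data.frame(rows), digits = 3, row.names = FALSE)

cat(sprintf("\nDL tau^2 = %g: FEM and REM coincide, and every fixed-effect route\n",
            dersimonian_laird_tau2(meta_input(c(adults, fx["scenario1"])))))
cat("(frequentist, Bayesian, MAP) concludes noninferiority.\n")
bre <- rows[grepl("^B MA RE", rows$method_label), ]
cat("Credible-interval widths under the prior battery:\n")
print(data.frame(prior = bre$tau2_info,
                 width = round(bre$ci_high - bre$ci_low, 3),
                 noninferior = bre$noninferior), row.names = FALSE)
cat("Assuming substantial heterogeneity widens the interval past the margin\n")
cat("even though the data are perfectly homogeneous.\n")
cat("Wrote results/homogeneous_battery.csv\n")
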