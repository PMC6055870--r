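Package: mapmeta
Title: Meta-Analytic-Predictive Borrowing for Paediatric Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for combining historical (adult) and new (paediatric)
    randomized two-arm binary-outcome trials on the log odds ratio scale.
    Implements frequentist fixed-effect and DerSimonian-Laird random-effects
    meta-analysis, Bayesian fixed- and random-effects meta-analysis under the
    normal-normal hierarchical model with half-normal and inverse-gamma
    heterogeneity priors (deterministic quadrature and exact binomial-logit
    MCMC engines), the two-step meta-analytic-predictive (MAP) procedure with
    its joint-model (MAC) counterpart, and significance/noninferiority
    decision rules producing labelled forest-table batteries for sensitivity
    analysis over heterogeneity priors.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
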