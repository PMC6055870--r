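---
title: "Borrowing adult evidence in paediatric trials: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Borrowing adult evidence in paediatric trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapmeta)
```

## The problem

A paediatric development programme rarely supports a self-standing proof of
efficacy: the prospective paediatric trial is small (here 53 patients per
arm) while the adult programme that justified licensing is large (three
trials of roughly 200–280 patients per arm). Any weighted combination of
the two therefore risks a *trivial* conclusion — one fully determined by the
adult data regardless of what the paediatric trial shows. `mapmeta`
implements the standard candidate analyses side by side so that exactly
this risk can be quantified: frequentist and Bayesian meta-analysis (fixed
and random effects), and the two-step meta-analytic-predictive (MAP)
procedure, all under an explicit battery of heterogeneity priors.

## Data model and effect scale

Each trial is a two-arm binomial experiment. With control event rate
$p_C$ and treatment rate $p_T$,

$$\mu = \operatorname{logit}(p_C), \qquad
  \operatorname{logit}(p_T) = \mu + \delta,$$

so the treatment effect $\delta$ is a log odds ratio. The observed effect
uses the cross-product estimate with the Woolf variance
$\widehat{\sigma}^2 = 1/a + 1/b + 1/c + 1/d$, which is treated as known in
every meta-analytic layer. Events are oriented as harms (treatment
failures) in the transplant example and as benefits (symptom relief) in
the dyspepsia example; orientation is carried as metadata and
noninferiority rules only apply to harm-oriented outcomes.

A continuity correction (0.5 added to all four cells) is applied only when
some cell is zero and only on request; none of the printed tables needs
it, but simulated small trials occasionally do. The exact-likelihood MCMC
engine needs no correction at all.

Confidence intervals are Wald intervals on the log OR with standard-normal
quantiles. P-values are two-sided by default; a one-sided option exists
because one published p-value in the worked examples (Opera, $p = .252$)
matches the one-sided normal test while the transplant-table p-values
match two-sided tests. A handful of printed interval bounds differ from
Wald/Woolf recomputation in the final digit; the published computation
method is not stated, and these digits are deliberately not chased.

## Meta-analysis layers

Frequentist pooling is inverse-variance weighting: $w_i = 1/\sigma_i^2$
(fixed effect) or $w_i^* = 1/(\sigma_i^2 + \hat\tau^2)$ (random effects).
The between-study variance estimator is DerSimonian–Laird,
$\hat\tau^2 = \max\{0, (Q - df)/(\sum w - \sum w^2/\sum w)\}$, chosen
because it is the conventional default and reproduces the worked examples'
behaviour ($\hat\tau^2 = 0$ in both homogeneous cases, so FEM $\equiv$
REM); REML is available behind `method = "REML"` but is not used by the
analysis scripts. Heterogeneity is tested with Cochran's $Q$ against
$\chi^2_{n-1}$ (upper tail). No Hartung–Knapp adjustment is applied — the
displayed intervals are plain Wald intervals.

The Bayesian layers use the normal-normal hierarchical model with vague
normal priors read as mean/**variance**: $\delta \sim N(0, 10)$ on the
overall effect and $\mu_i \sim N(0, 4)$ on control logits (an SD
parameterization is available via `normal_prior(..., parameterization =
"sd")` and is labelled loudly when printed). With these priors the Bayesian
fixed-effect posterior is numerically indistinguishable from the
frequentist result, which the test suite asserts on every fixture.

## Heterogeneity priors

Five informative priors span the sensitivity range, parameterized so that
their nominal heterogeneity reproduces the conventional translation table:

```{r}
t(sapply(default_het_priors(), function(p) unlist(nominal_heterogeneity(p))))
```

Conventions, decided once: the inverse-gamma is read scale-first
(`IG(1/3, 1)` = scale 1/3, shape 1 on $\tau^2$, i.e. precision
$\sim$ Gamma(1, rate 1/3)), because scale/shape then reproduces the
tabulated representative values 0.33, 0.14, 0.001 exactly — the strict
mean of $\tau^2$ is undefined at shape 1, so the "expected heterogeneity"
is this nominal value, not a moment. The half-normal uses the squared
prior mean $(E\tau)^2 = 2s^2/\pi$, which reproduces 0.16 for HN(0.5); no
standard moment reproduces the commonly quoted 0.61 for HN(1) exactly
(the value here is 0.637), and this is documented rather than forced. The
trial-ratio translation is fixed as
$OR_1/OR_2 = \exp(2 \cdot 1.96\,\sqrt{\tau^2_{\text{nominal}}})$, the
ratio of the 97.5th to 2.5th percentile of trial-level odds ratios, which
matches the tabulated integers within their loose rounding. Both
inverse-gamma argument orders are accepted in configuration with an
explicit keyword to prevent silent misreads.

## Quadrature engine

For a fixed $\tau$ the mean integrates out analytically, giving the
closed-form marginal likelihood $m(\text{data}\mid\tau)$ and conjugate
conditional posterior; the marginal posterior of $\tau$ is then
$p(\tau\mid\text{data}) \propto p(\tau)\, m(\text{data}\mid\tau)$ on a
grid, and the effect posterior is the corresponding mixture of normals.
Numerical choices: 400 $\tau$ points from 0 to the prior's 99.99%
quantile (capped at 10, relevant for the heavy-tailed inverse-gammas); an
800-point effect grid spanning every conditional mean $\pm 8$ conditional
SDs, so both tails fall below $10^{-6}$ of the peak; trapezoid rule
throughout, with densities renormalized on the grid. Doubling both
resolutions moves posterior means by less than $10^{-4}$ (asserted in the
tests). Summaries are posterior mean, median and *central* (equal-tailed)
credible intervals, matching the symmetric interval displays of the
worked examples; highest-density intervals exist behind
`interval = "hdi"` because the half-normal MAP posteriors are visibly
skewed, but they are not used in any reported table, and reported point
estimates are medians for the same reason.

## MCMC engine

The exact-likelihood engine is an adaptive Metropolis-within-Gibbs sampler
on the binomial-logit model (per-parameter Gaussian random walks tuned to
20–40% acceptance during burn-in; the hierarchical mean has a conjugate
Gibbs step). Defaults: 4 chains, 10,000 iterations, 50% burn-in, seed
mandatory. Convergence is enforced, not just reported: any split-
$\widehat R > 1.05$ raises an error carrying the chain statistics.
The two engines use *different likelihoods* (exact binomial vs normal
approximation), so their agreement tolerance on small fixtures is
$\max(0.02,\ 3\,\text{MCSE})$, while a large simulated trial (5,000 per
arm, where the normal approximation is excellent) must agree within 0.01.

## MAP and its joint-model oracle

Step one builds the posterior-predictive distribution of a new trial's
effect from the historical set:
$p(\delta_{new}\mid \text{hist}) = \iint N(\delta_{new}\mid\theta,\tau^2)\,
p(\theta,\tau\mid\text{hist})\,d\theta\,d\tau$, inner integral closed-form,
outer on the $\tau$ grid. Step two multiplies in the new trial's normal
likelihood — no heterogeneity prior appears in step two. Design choices:

* The hierarchical mean $\theta$ carries an improper flat prior by
  default in MAP/MAC construction, under which the known-$\tau$ closed
  forms $N(\hat\delta_H, \sigma_H^2)$ and
  $N(\hat\delta_H, 2\tau^2 + \sigma_H^2)$ hold *exactly* (the predictive
  variance counts the between-trial term twice: once for the historical,
  once for the new trial). A proper prior can be supplied; the vague
  $N(0,10)$ changes results only in the third decimal.
* The sequential pipeline must equal the one-step joint (MAC) analysis of
  all trials — the central correctness property of the construction. The
  package computes the MAC posterior by an independent route (posterior of
  $\tau$ from all studies, conditional shrinkage
  $w\,\hat\delta_{new} + (1-w)\,\theta$ with $w = \tau^2/(\tau^2 +
  \sigma^2_{new})$) and the tests assert agreement within $5\times10^{-3}$
  on every fixture × prior combination; observed agreement is
  $\sim 10^{-4}$ or better.
* The default MAP battery drops IG(1/1000,1): at nominal $\tau^2 = 0.001$
  its row duplicates the fixed-effect MAP row, giving the documented
  15-row layout for the two-trial battery.

## Monotonicity across priors: within families only

Interval width and borrowing strength are monotone in nominal
heterogeneity *within* each prior family (asserted on the chains
IG(1/1000,1) → IG(1/7,1) → IG(1/3,1) and HN(0.5) → HN(1), plus the
cross-family triple IG(1/1000,1) < HN(0.5) < HN(1)). A strict total order
across all five priors by nominal $\tau^2$ does **not** hold and is not
asserted: the inverse-gamma's thin lower tail keeps $\tau$ away from zero
(little mass near homogeneity), so IG(1/7,1) produces wider intervals and
weaker borrowing than half-normals of similar or larger nominal
heterogeneity, whose substantial mass near $\tau = 0$ — and resulting
skewed posteriors — give the historical data more weight. This is a
genuine feature of the prior shapes, visible in the heterogeneous-case
battery (`analysis/04`), not a numerical artefact.

## Decision rules

Significance: the two-sided 95% interval excludes 0. Noninferiority: the
upper bound falls strictly below the margin (0.43 log OR by default, the
translation of a 10 percentage-point risk margin at a control rate near
31% — exact value 0.436 at 31.1%, quoted conventionally as 0.43);
equality at the margin fails. This is equivalent to a one-sided 2.5% test
and matches the visual rule of forest displays. Method labels form a fixed
vocabulary (`F MA FE`, `B MA RE HN(1)`, `B MAP RE IG(1/3,1)`, ...) so
that rows are addressable downstream, and the battery writer emits a
stable CSV whose decision flags are pure functions of the numeric columns.

## What the generator emulates — and what it does not

`simulate_programme()` emulates the transplant extrapolation setting:
three adult trials (195/195/277 per arm), one paediatric trial (53 per
arm), a shared control failure rate of 0.28 (the pooled adult control rate
is 27.6–31.1% across trials) and a true log OR of 0, with optional
exchangeable heterogeneity $\delta_i \sim N(\delta, \tau^2)$ applied on
the logit scale. Random streams are split deterministically per study, so
extending a programme never perturbs existing trials. The generator does
*not* emulate differing control rates across studies, non-exchangeable
(e.g. systematically shifted) paediatric effects, overdispersion, or
missingness — so passing calibration here demonstrates internal
consistency of the models, not robustness to those real-data features.

Calibration runs use 200 replicates per heterogeneity level
($\tau \in \{0, 0.3, 0.6\}$) with the correctly specified known-$\tau$
joint model, and a 200-replicate simulation-based-calibration check of the
quadrature engine at reduced grid resolution; these sizes keep the full
suite comfortably under a minute per check while leaving Monte-Carlo error
well inside the asserted bands.

## Known limitations

* Only the log OR scale is supported (no risk difference/ratio, no exact
  conditional inference, no individual-patient data).
* Heterogeneity priors are limited to the half-normal, inverse-gamma and
  point-mass families used in the sensitivity battery.
* Power priors and robust mixture MAP priors are out of scope; the
  random-effects MAP with its heterogeneity battery covers the discounting
  role they would play.
* Two published heterogeneity anchors do not reproduce from the printed
  counts (a Bond/Opera heterogeneity p of .039 vs the recomputed .044, and
  a $\hat\tau^2$ plug-in example); recomputed values are cross-checked
  against `metafor` instead and the discrepancies are documented, not
  fitted.
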