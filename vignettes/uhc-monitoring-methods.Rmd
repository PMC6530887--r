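---
title: "Methods: monitoring universal health coverage from household surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monitoring universal health coverage from household surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhcmonitor)
```

# Scope

`uhcmonitor` estimates the two components of universal health coverage
(UHC) monitoring — health-service coverage and financial risk protection —
from household-survey microdata, quantifies wealth-related inequality, and
projects trends to 2030 with probabilities of meeting the UHC targets (at
least 80% essential-service coverage; universal protection from
out-of-pocket payments). Restricted-access survey families (DHS-type
coverage surveys, GLSS-type consumption surveys) are emulated by a seeded
synthetic generator with known ground truth, so every stage is exercisable
and testable offline.

# The synthetic survey generator

The generator defines the study conditions for all tests; it is first-class,
tested code, not a fixture.

**Coverage survey.** For each wave (defaults 1993, 1998, 2003, 2008, 2014) a
two-stage sample is drawn: `n_clusters` clusters (default 100) of
`households_per_cluster` households (default 20). Latent household wealth is
a cluster random effect plus household noise, standard normal marginally,
with intra-cluster correlation `wealth_icc` (default 0.3) — this induces the
design effects that the cluster-linearized variance estimator must detect.
Ten binary asset indicators are Bernoulli with logit-linear response in
wealth (item-specific difficulties spanning −1.2…1.2 and loadings 0.8…1.6),
so the first principal component of the asset battery recovers the wealth
ranking. Each service-use outcome is Bernoulli with
`logit p = a0 + b (year − year0) + g · wealth + region offset`. The default
`a0`, `b`, `g` per indicator mimic the published Ghanaian trajectories
(e.g. near-universal childhood immunization by 2015; sanitation and
institutional delivery with the steepest wealth gradients, `g` = 1.0–1.2
logit/SD; bed-net and postnatal-care items entering the instrument only in
2003). Sampling weights are log-normal with coefficient of variation 0.25
(≤ 0.3, avoiding extreme-weight pathologies) and are normalized to sum to
the per-year sample size.

**Expenditure survey.** Four waves (1991, 1998, 2005, 2012; default 3000
households each). Household size is `1 + Poisson(3.3)`; per-capita total
consumption is log-normal (`meanlog = log 800` drifting +0.04/yr, `sdlog`
0.65, currency units arbitrary); the food share is logit-normal around a
wave mean declining 0.62 → 0.46 (households spend relatively more on
non-food over time). Out-of-pocket (OOP) health spending is zero-inflated
(`p_any` = 0.65) log-normal with wave locations 4.70 → 4.37, capped at
non-food expenditure so the accounting identity `food + nonfood = total`
and `oop ≤ nonfood` hold by construction. These locations were chosen
analytically, once, so catastrophic-expenditure incidence declines across
waves from roughly 15% to a few percent — the scenario the package's
monitoring questions are about. Mild regional offsets on the OOP location
create subnational contrast.

What the generator does **not** emulate: survey nonresponse, recall error,
questionnaire skip patterns and eligibility windows (eligibility is a
row-level missing outcome), seasonal effects, or real DHS/GLSS variable
naming. Passing tests therefore demonstrate correctness of the estimators
under a clean probability model, not robustness to real-world measurement
problems.

# Estimation

**Coverage proportions.** `p̂ = Σ w y / Σ w` over eligible (non-missing)
rows. The variance uses Taylor linearization with clusters as primary
sampling units within a year: the score residuals `w(y − p̂)` are totalled
per cluster and `var(p̂) = m/(m−1) Σ_c z_c² / (Σw)²`. The 95% interval is
computed on the logit scale and back-transformed, which respects the [0,1]
range. Boundary estimates (p̂ of exactly 0 or 1) are reported exactly, but
for interval construction and downstream logit transforms receive a
half-success continuity adjustment `(p n_eff + 0.5)/(n_eff + 1)` at the
effective sample size `n_eff = (Σw)²/Σw²`. The interval method for raw
survey proportions is a documented default (logit-scale Wald with
linearized variance). Consumption surveys carry no cluster identifier, so
households are treated as independent sampling units there.

**Wealth index and quintiles.** Assets are standardized to weighted mean 0
and variance 1; the score is the first eigenvector of the (unweighted)
second-moment matrix applied to the standardized battery, signed to
correlate positively with the raw asset count. Weighted standardization
makes the score's weighted mean exactly zero; the eigendecomposition itself
is unweighted while quintile cut points are population-weighted — the
conventional DHS-style compromise, recorded here as the package's default.
A household is assigned to the fifth of the cumulative weight distribution
containing its weighted-rank midpoint (ties broken by stable input order),
which handles dominant-weight households deterministically and keeps every
quintile's weighted share within one household's weight of 20%. Zero-
variance assets are dropped with a warning; an all-constant battery is an
error. The index is built separately per survey year, as each survey
carries its own index.

**Composite indices.** Indicator estimates are pooled per year × group by
DerSimonian–Laird random-effects meta-analysis on the percent scale of the
point estimates; with equal standard errors this reduces to the arithmetic
mean, matching the "mean value" reading of a composite index. A logit-scale
pooling option exists behind the `scale` flag; percent is the default
because the composite is defined as a mean of coverages. The composite
prevention index uses exactly nine prevention indicators (four antenatal
visits, exclusive breastfeeding, family-planning needs satisfied, improved
water, adequate sanitation, BCG, measles, DPT3, Polio3); the treatment
index uses all four treatment indicators; the CCI uses the standard Boerma
four-specialty weighting with DPT3 double-weighted.

**Financial hardship.** The OOP share is `oop / nonfood` (share 1 with a
warning when non-food is zero but OOP positive; 0 when both are zero).
Catastrophe is a *strict* exceedance of the threshold (default 25% of
non-food consumption; configurable, e.g. `{0.10, 0.25, 0.40}`). The poverty
line is the weighted mean per-capita food expenditure of households whose
food share lies in the weighted 45th–55th percentile band; weighted
percentiles use the lower-inclusive inverse-CDF (step-function) definition,
which is deterministic across implementations, and an empty band is widened
symmetrically by one percentile until nonempty. A household is impoverished
when it was not poor before paying (per-capita total ≥ poverty line) and
its per-capita total net of OOP falls below the line; pre-payment-poor
households are excluded from impoverishment, the standard guideline
reading of the definition. Hardship is the union of catastrophe and
impoverishment at the household level. Comparisons are per-capita
(household totals over household size); an equivalence-scale alternative is
deliberately out of scope. Poverty lines are computed per wave in nominal
terms; no CPI deflation is attempted.

**Inequality (SII/RII).** Quintile-level outcomes (percent) are regressed
on the quintiles' relative-rank midpoints (ridits) by weighted least
squares with quintile population shares as weights — quintile-level rather
than household-level regression matches the reporting granularity and keeps
the posterior-draw path simple. SII is the fitted difference between rank 1
and rank 0 (percentage points); RII is the ratio fitted(1)/fitted(0),
richest over poorest, so pro-rich coverage gives RII > 1 and a pro-poor
burden like catastrophic spending gives RII < 1. The identity link (not
logistic) is used because SII is defined in percentage points. Under steep
gradients the linear fit can leave the positive orthant at a rank extreme;
the RII is then reported as missing rather than as a meaningless negative
ratio. Credible intervals come from applying the closed-form WLS to each
joint posterior draw of the five quintile trajectories; draws must be
jointly indexed across quintiles, otherwise the between-quintile posterior
dependence is destroyed.

# The Bayesian trend model

All proportions are logit-transformed; per indicator × group,
`y_i = logit(p_i)` is modelled as Gaussian around `α + β (t_i − t_0)` with
a single residual variance σ² and the non-informative prior `∝ 1/σ²`. The
year covariate is centered at the first observed year for conditioning
(results are invariant). The likelihood is unweighted across survey years;
a per-survey variance-weighted option is a possible extension but is not
the default because the trend regression is specified on the transformed
point estimates. "Predicted coverage" is the posterior of the systematic
trend `inv_logit(α + β t*)` without residual noise — projecting the smooth
trajectory — with a new-observation predictive option behind a flag.

**Exact conjugate oracle.** Under the flat prior the posterior is
normal–inverse-gamma in closed form: σ² is scaled-inverse-χ² with n−p
degrees of freedom around the residual mean square and the coefficients are
conditionally normal around the least-squares solution.
`fit_trend_conjugate()` samples this joint exactly and serves as the
independent oracle for the MCMC sampler in the tests.

**Gibbs sampler.** `fit_trend_mcmc()` alternates the two exact full
conditionals (coefficients given σ²; σ² given coefficients, a scaled
inverse-χ² with n degrees of freedom around RSS(b)/n). Two chains start
from overdispersed residual-variance values; 5000 burn-in iterations per
chain are discarded and 1000 draws retained across chains by default.
Convergence requires the Gelman–Rubin potential scale reduction factor
`PSRF = sqrt(((n−1)/n · W + B/n)/W)` of every parameter (coefficients and
log σ²) to be at most 1.02; otherwise the burn-in is doubled and the
sampler rerun up to 200 000 iterations per chain, after which the
nonconvergence is flagged, never silently ignored. Degenerate chains
(within-chain variance 0) define PSRF = 1.

**Numerical choices.** Exact-line data (zero residual variance) floor σ² at
1e−8 on the logit scale so the conjugate draw stays well-defined, with a
warning. Proportions of exactly 0/1 are continuity-adjusted upstream (see
above) because the logit is undefined at the boundary. Grouped designs use
the first group label alphabetically as reference; a group observed in a
single year is an error naming the group. Rank-deficient designs error
rather than silently dropping terms.

**Model comparison and summaries.** For quintile/region-adjusted models,
DIC (`Dbar + pD`, with `pD = Dbar − D(posterior means)`) is computed for
the model with and without group × year interaction and the smaller
penalized deviance wins; both values are always reported, and selection is
aborted if either fit failed to converge. Projections are summarized by the
posterior mean and central 95% credible interval on the percent scale. Note
that for heavily skewed backcasts far outside the observed years a
posterior mean can fall slightly outside the central percentile interval —
a property of means under skew, not an error. The probability of meeting
the 80% coverage target is the fraction of draws with projected 2030
coverage ≥ 0.80. The 100% financial-risk-protection target has probability
zero under any continuous posterior, so it is operationalized as projected
incidence below ε = 1 percentage point by 2030 (ε is configurable and
logged in the outputs). The annual rate of change is the endpoint geometric
rate `100·[(c_end/c_start)^(1/(end−start)) − 1]` per draw; this endpoint
definition reproduces the printed rates for slowly-moving indicators but is
known to understate rates reported for indicators with extreme early
backcasts, an ambiguity documented rather than resolved.

# Problem sizes and runtime

The default test and demo scenario uses 40 clusters × 12 households × 5
coverage waves (2400 households) and 1200 households × 4 consumption waves,
with 1000 retained draws per fit — sizes chosen so the full pipeline runs
in seconds while leaving all estimators in their asymptotically meaningful
regimes. The calibration study uses 200 simulated five-wave datasets; the
oracle-equivalence check uses 8000–20 000 draws per sampler because with
n − p = 3 residual degrees of freedom the coefficient marginals are
t₃-distributed and moment comparisons need replication-based Monte-Carlo
standard errors (normal-theory formulas assume finite fourth moments).

# Known limitations

* Indicator definitions are simplified to row-level binary outcomes with
  missingness; real DHS denominators (birth recency windows, card-vs-recall
  vaccination) are not reconstructed.
* The trend model is linear on the logit scale with a single residual
  variance; splines, hierarchical pooling across indicators, and
  informative priors are out of scope.
* SII/RII use the identity link on quintile aggregates; concentration
  indices and household-level rank regressions are not provided.
* Poverty lines are nominal per wave; no CPI adjustment, intensity measures
  or normative ($/day) lines.
* The composite indices pool point estimates on the percent scale by
  default; between-indicator heterogeneity (τ²) can be large, and the CCI
  is reported without an uncertainty interval when built directly from
  point estimates.
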