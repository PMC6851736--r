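---
title: "Estimating supply-side cost-effectiveness thresholds from hospital panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating supply-side cost-effectiveness thresholds from hospital panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qalythreshold)
```

## The estimand

`qalythreshold` estimates the opportunity cost of hospital spending:
the euros of marginal spending needed to avert one QALY of health loss
for the average patient group. The analysis unit is the patient group —
a gender × five-year-age-band × disease-group cell — observed over a
short panel of calendar years. With 2 genders, 21 age bands and 405
disease groups the full cross-classification has 17,010 cells; in
national claims data most, but not all, contain claims.

Health loss is measured as total QALY loss per group-year,

$$Q_{it} = Q^{morb}_{it} + Q^{mort}_{it},$$

and related to corrected spending $C_{it}$ and patient numbers
$N_{it}$ through a translog production function with group fixed
effects:

$$\log Q_{it} = a_i + b\,T_t + c_1 \log C_{it} + c_2 (\log C_{it})^2 +
d_1 \log N_{it} + d_2 (\log N_{it})^2 + c_3 \log C_{it}\log N_{it} +
u_{it}.$$

The translog is a second-order Taylor approximation of an arbitrary
production function around the sample mean: it assumes
differentiability and diminishing marginal returns near the mean but
imposes no global functional form, which matters when patient groups
are as heterogeneous as an entire hospital sector. Its derivative
gives a point elasticity that varies with input levels,

$$e = \frac{\partial \log Q}{\partial \log C} = c_1 + 2 c_2\,
\overline{\log C} + c_3\, \overline{\log N},$$

evaluated at the *means of the logs*. Conversion to euros per QALY
happens at the *arithmetic* means:

$$\text{threshold} = \frac{\bar C}{|e| \cdot \bar Q}, \qquad e < 0.$$

Both conventions are deliberate and different: log-spending in claims
data is heavily skewed, so the mean of logs and the log of the mean
differ by an order of magnitude in euro terms; the elasticity is a
statement about the typical (log-scale) group, while the euro
conversion is a statement about the average euro and average QALY.

**Coefficient convention.** `c2` and `d2` are the regression
coefficients on the squared regressors. In the Taylor form with
explicit $\tfrac12$ factors they equal half the curvature terms, which
is why the elasticity formula carries the factor $2 c_2$. Reading a
quadratic coefficient from a regression table and forgetting this
factor changes the elasticity materially; `elasticity_at()` applies
the convention internally.

## The data transformations

**Morbidity loss (questionnaires → QALYs).** EQ-5D profiles are scored
by an additive tariff (`score_eq5d()`): full health minus a constant
deduction for any departure from full health, per-dimension decrements
for levels 2 and 3, and an extra N3 decrement when any dimension is at
its worst level. Tariff coefficients are a configuration input
(`tariff.yaml`) — value sets differ by country and should never be
hardcoded. A single pooled least-squares regression of scored utility
on stratum intercepts, per-stratum hospital-visit effects and
per-stratum visit×year interactions yields, per (gender, age band):
the patient/non-patient utility gap (interpretable as the health gain
the sector could still achieve per patient, in QALYs/year) and the
annual trend in patient utility. Both are reported on the *loss*
scale: `gap` positive when patients are worse off, `trend` the annual
change in per-patient loss. Per-patient loss times the group's
*base-year* patient count gives group morbidity loss; the base-year
count is used for all years so that within-group changes reflect only
the estimated trend, not patient-count churn. This assumes patients'
pre-hospital health is constant over the panel — background health
improvements are meant to show up in $N_{it}$, not in the gap.

**Mortality loss (deaths → QALYs).** Each death forfeits the
stratum's healthy life expectancy, discounted to present value
(`discounted_hle()`) and shrunk by the disease's burden-of-disease
weight: a weight of 0.1 credits 10% fewer healthy life years, since a
patient whose death is averted does not return to full population
health. Weights live in [0, 1]; diseases without a published weight
receive the (gender-specific, when available) mean of the others.

**Discounting timing.** Annuity-due: the first year is undiscounted,
year $t$ is discounted by $(1+r)^{-t}$, and the final fractional year
is pro-rated at its year's factor. This convention reproduces the
exact identity NPV$(h, 0) = h$ and is the common HTA choice; whether a
given published life table used annuity-due or annuity-immediate
timing generally cannot be recovered from its printed values, so the
choice is fixed here and documented rather than configurable. The
default rate is 1.5%/year (Dutch HTA guidance), with a sweep over
{0, 1.5, 3, 5}% as sensitivity analysis; the threshold rises with the
rate because most mortality benefits lie in the future.

**Spending correction (reverse causality).** Raw group spending
mechanically contains its decedents' last-year-of-life (LYoL) costs,
so lower mortality would lower spending even with no causal effect of
spending on health. The package subtracts deaths × stratum LYoL cost:
$S_{it} = LYoL_{it} + C_{it}$. Cells where the correction exhausts
spending ($C \le 0$) cannot be log-transformed; they are *excluded*,
never floored at a small positive value — flooring would fabricate
spending and distort the fit more than the (small, reported) censoring
the exclusion causes. The exclusion fraction is reported per year.
LYoL costs are age/gender-specific only; a disease-specific breakdown
would be better but is rarely available.

## Estimation and uncertainty

**Within estimator.** The fixed effects are absorbed by entity
demeaning; `fit_fixed_effects()` solves the demeaned least-squares
problem directly and is numerically identical (≤ 1e-8) to least
squares with one indicator per group, which the test suite asserts
against `lm()` as an independent oracle. Degrees of freedom, the
within-$R^2$ and the F statistic account for the absorbed group means.
Groups reduced to a single observation carry no within information and
drop out. Conventional homoskedastic standard errors are the default
(matching the usual presentation of such fits); group-clustered robust
errors are available behind a flag. Unbalanced panels are allowed:
an excluded cell drops only that group-year.

**Cluster bootstrap.** Groups (entire time series) are resampled with
replacement, preserving the within-group dependence the fixed effect
models. Each replicate refits the model and re-evaluates elasticity
and threshold *at the original sample's means*: the replicate spread
thus reflects coefficient uncertainty at a fixed evaluation point.
This choice makes the zero-noise limit exact — a noiseless panel
refits to identical coefficients and the bootstrap SE collapses to
0 — whereas resampling the evaluation point too would manufacture
spread out of composition changes. The normal-approximation interval
(point ± 1.96 SE) is reported alongside a percentile interval.
Replicates with non-negative elasticity leave the threshold undefined;
they are excluded from the SE and counted.

**Monte Carlo.** The outcome construction rests on estimated
parameters; `run_monte_carlo()` redraws them, rebuilds outcomes and
corrected spending, refits, and recomputes the threshold per draw.
Distributions: healthy life expectancy and LYoL costs normal with
their table SDs (10% of the mean is the conventional LYoL assumption),
gap/trend normal with their regression SEs, and burden weights
*uniform* on [BoD, 1] — the distribution family for "between the
point value and 1" is not standardised, and uniform is the
maximum-entropy reading of that support. Normal draws are truncated at
admissible bounds (HLE ≥ 0, LYoL ≥ 0) rather than resampled, keeping
each draw index a deterministic function of the seed. Each parameter
is also varied alone for a variance decomposition. Regression-
coefficient uncertainty is deliberately *not* part of the Monte Carlo
(the bootstrap covers it); combining the two as a sum of variances is
an approximation that ignores their covariance and should be labelled
as such when reported.

## The synthetic-data generator

No public microdata exist at this granularity, so the generator is a
first-class, tested module, not a fixture. It emulates: the
gender × age × disease panel structure; log-normal corrected spending
with a wide between-group spread (mean log spending ≈ 11.97 but
arithmetic mean ≈ €1.7M, matching the skew of real claims); log-normal
patient counts; group fixed effects; a common negative time trend;
binomial deaths with age-graded rates whose LYoL costs are embedded in
raw spending ($S = C + D \cdot LYoL$, making the correction exactly
invertible); stationary AR(1) year-to-year innovations within groups
(autocorrelation 0.3 — administrative panels are persistent, though
the true short-panel dynamics are unknowable from three years); and a
questionnaire sample whose patient/non-patient scored-utility gap and
trend match the planted values in expectation, via two-point mixtures
of anchor profiles. Each logical sub-draw (fixed effects, counts,
noise, deaths, …) runs on its own seeded stream.

Two generator choices deserve emphasis:

* **Latent outcome vs constructed outcome.** The generator draws
  $\log Q$ *exactly* from the translog truth — this latent outcome
  panel (`latent_outcome_panel()`) is the oracle on which coefficient
  and elasticity recovery are tested. The questionnaire/mortality
  *construction* path produces a different $Q$ (gap × patients +
  deaths × HLE), which cannot embody an arbitrary planted coefficient
  vector; the full CSV pipeline is therefore tested for determinism,
  accounting identities, gap recovery and a correctly signed
  elasticity, not for coefficient recovery.
* **A planted causal gradient.** Death rates are damped by the
  group's within-year spending innovation (semi-elasticity 0.5 by
  default): spending above a group's own level averts deaths. Without
  it, the constructed outcome would be uncorrelated with spending
  within groups and the pipeline would — correctly — refuse to report
  a threshold from a non-negative elasticity.

What the generator does *not* emulate: real disease epidemiology,
multimorbidity overlap between groups, censoring of very ill
questionnaire respondents, cost-shifting in claims, or magnitudes
calibrated beyond order-of-magnitude plausibility. Passing tests
demonstrate the estimator recovers known structure under these ideal
conditions; they do not certify the behavioural assumptions (patient
counts as health-trend proxy, LYoL independence of averted-death
composition) on real data.

**Default noise scale.** The idiosyncratic SD on $\log Q$ defaults to
0.06 with within-group log-spending innovations of SD 0.35. These were
set so that the package's reference recovery benchmark — 2,000 groups
× 3 years, 50 seeded replicates — identifies the elasticity at the
mean within 5% relative error in at least 80% of replicates and every
coefficient within 3 reported SEs in at least 90% (the test suite runs
exactly this benchmark; at these sizes it takes a few seconds). Real
claims panels are far noisier; recovering elasticities there leans on
sample sizes an order of magnitude larger.

## Numerical and degenerate-input conventions

* Natural logs throughout; elasticities are invariant to rescaling the
  spending unit (asserted numerically in the tests).
* Cells with nonpositive $Q$, $C$ or patient count are excluded with a
  recorded reason before the design matrix is built; a nonpositive
  value reaching the design stage is an internal error, not a silent
  drop.
* Perfect collinearity after demeaning raises an error naming the
  offending columns.
* A non-negative elasticity is an error wherever a threshold would be
  derived from it — a threshold from $e \ge 0$ is meaningless, and
  silently reporting its absolute value would invert the policy
  conclusion.
* Strata whose questionnaire sample contains only patients or only
  non-patients are flagged and excluded from the morbidity fit;
  downstream, groups in such strata are excluded with reason.
* Subgroup thresholds default to evaluating the *pooled* fit at
  stratum-specific means (refitting per stratum is available): the
  Taylor approximation degrades away from the pooled mean, and
  per-stratum refits on thin strata are unstable, so the pooled
  evaluation is the safer default. An optional linear-in-age
  extrapolation of morbidity estimates to uncovered strata exists
  behind a configuration switch and is off by default.

## Problem sizes

The test suite and examples run on deliberately small worlds: 8-60
diseases × 4-6 age bands (a few hundred to a few thousand groups),
100-1,500 questionnaire respondents per stratum, 10-100 bootstrap
replicates and up to 500 Monte Carlo draws — sizes chosen as the
smallest at which each statistical property is cleanly visible. The
full-scale configuration (405 diseases, 10,000 draws, 100 replicates)
runs through the same code paths unchanged.

## Known limitations

* Dropping nonpositive-$C$ cells is a censoring mechanism; at
  realistic scales it affects well under 1% of cells, but a formal
  truncation correction is future work.
* Single-year LYoL correction only: with lagged or multi-year models
  the correction would need to track spending in additional years
  before death.
* The per-patient morbidity gap is not disease-specific, which blurs
  disease-level subgroup thresholds.
* The bootstrap and Monte Carlo variance components are combined, if
  at all, by simple addition; their dependence is not modelled.
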