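---
title: "Methods: within-trial cost-utility analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-utility analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The analysis model

`trialcea` implements a cost-utility analysis conducted alongside a
two-arm randomised trial, from the perspective of a health system plus
personal social services. Per participant it produces a total cost over
the trial horizon and a quality-adjusted life year (QALY) measure; per
trial it produces the incremental pair (ΔC, ΔE), its joint bootstrap
distribution, and decision-oriented summaries: the incremental
cost-effectiveness ratio (ICER = ΔC/ΔE), net monetary benefit
(NMB(λ) = λ·ΔE − ΔC), and the cost-effectiveness acceptability curve
(CEAC), the probability that the intervention is the optimal choice as a
function of the ceiling ratio λ a decision maker would pay per QALY.

Assumptions inherited from the trial design it targets:

- a short horizon (20 weeks), so neither costs nor QALYs are discounted;
- EQ-5D measured at fixed weeks (0, 10, 20), with linear change in
  utility between measurements;
- resource use recorded as item counts or durations per assessment
  period, valued by multiplying by a unit-cost tariff;
- inference about *mean* costs, despite skewness, because the payer's
  budget depends on the mean — hence t-tests and mean-difference
  bootstraps rather than rank methods.

## Costing

Money is held internally in integer pence and converted to pounds only at
the interface. This makes the conservation identities exact: per-category
sums equal the sum of per-record costs to the penny, and
`total_healthcare = medication + acute + primary`,
`total_combined = total_healthcare + social` hold without floating-point
drift. Each record is rounded to the penny before summation.

The tariff stores, for every item, both the price and the derivation it
came from (`multiply`, `divide`, `per_hour`, or `identity`), and
re-derives every price on construction, refusing a tariff whose stored
and derived prices disagree. Published tariffs are not uniform in their
rounding: most entries round half-up, but two (£35/3 printed as £11.66,
and 25 minutes at £40/h printed as £16.66) are truncations, so rounding
is a per-entry flag rather than a global convention.

Two tariff conventions deserve note. Outpatient appointments carry
different first-attendance (£55) and follow-up (£71) prices; since
recorded contact streams rarely distinguish them, the generator and the
default analyses use the follow-up price. Hospitalisation *events* carry
a zero price: they are analysed as contact counts, while their cost
enters through inpatient bed days.

The intervention micro-costing sums venue hire, therapist time, therapist
travel and equipment for the delivered course of groups and divides by
the number randomised to the intervention (all-attend assumption). The
alternative-group-size scenario scales the components that vary with the
number of groups run — venue, therapist time, therapist travel — by
`ceiling(n/new_size) / ceiling(n/old_size)` while equipment is fixed.
This is a modelling assumption (courses are booked per group); other
accounting conventions would shift the scenario figure by a pound or two,
which is why the scenario output is presented as an approximation.

## QALYs

`qaly_auc()` integrates the piecewise-linear utility curve over the
horizon and divides by the weeks in a year. The year length defaults to
52 weeks and is configurable; no convention is universal, and trial
reports often do not state theirs. The computation is an exact linear
functional of the utilities — the dot product with trapezoid weights
`qaly_weights()` returns — which the tests exploit as an independent
oracle.

Deaths: a participant who dies is registered at zero utility *from the
assessment period in which the death occurred*. The default
(`death_rule = "assessment"`) therefore zeroes every scheduled assessment
at or after the death week and interpolates linearly from the last
pre-death assessment; the stricter literal alternative
(`death_rule = "exact"`), which drops to zero at the death date itself,
is available behind a flag and always yields fewer QALYs. Both leave the
trajectory "complete": death is a resolution, not missingness.

A missing utility not explained by death is an error at this layer; the
caller routes such participants to the missing-data module.

## Between-arm estimation

- Mean differences use the Welch t-test by default (the pooled-variance
  form is a flag): with unequal arm sizes and skewed costs, assuming
  equal variances buys nothing.
- The bootstrap is stratified: every replicate resamples participants
  with replacement *within* arm, preserving both arm sizes. Intervals are
  bias-corrected (BC) percentile intervals: with
  z₀ = Φ⁻¹(P(θ* < θ̂)), the endpoints are the bootstrap quantiles at
  Φ(2z₀ ± z₀.₉₇₅). The acceleration term of BCa is deliberately omitted.
  Numerical choices: quantile type 7 (R's default); the proportion below
  is clamped to [1/(B+1), B/(B+1)] so z₀ stays finite; fully degenerate
  replicate sets collapse the interval to the point value and set a flag.
- Count contrasts use the closed-form Poisson rate ratio with log-scale
  Wald variance 1/a + 1/b (equivalent to two-group Poisson regression
  with a log exposure offset), and binary any-use contrasts use the Katz
  relative risk with variance 1/a − 1/nₐ + 1/b − 1/n_b. A zero count in
  either arm makes the log-scale interval undefined; the result is a
  first-class "not calculable" state, not an exception, because that is
  how trial resource-use tables report such cells.
- Baseline adjustment is ordinary least squares of outcome on an arm
  indicator and the baseline value. A constant baseline carries no
  information and is dropped (the estimate is then the unadjusted
  difference); a baseline collinear with the arm indicator is an error.

## The joint cost-effectiveness layer

`bootstrap_joint()` computes each replicate's (ΔC, ΔE) from the *same*
resampled participants, preserving the within-person correlation between
costs and outcome — resampling the two margins independently would
understate or overstate the variance of NMB depending on the sign of that
correlation.

The CEAC at λ is the fraction of replicates with strictly positive NMB;
ties, a measure-zero event for continuous data, count as not
cost-effective, which keeps the intervention and control curves exactly
complementary. Endpoint identities are exact by construction: at λ = 0
the curve equals the fraction of replicates with ΔC < 0, and its large-λ
limit is the fraction with ΔE > 0. The default grid runs £0–£100,000 in
£500 steps with the decision threshold at £20,000/QALY, the lower bound
of the conventional UK acceptability range. Negative ICERs are always
reported together with their CE-plane quadrant, since the ratio's sign
alone cannot distinguish "cheaper and better" from "dearer and worse";
the headline output is the CEAC.

`write_ceac_csv()` fixes column order and decimal formatting so the file
is byte-identical under a fixed seed — useful for regression-testing a
pipeline.

## Missing data

Complete-case selection keeps participants complete on both total costs
and QALYs and reports a baseline comparison of the available and missing
groups (t-tests for continuous characteristics; chi-square, or Fisher's
exact test when an expected cell is below 5, for categorical).

Two sensitivity analyses:

- **LOCF**: a missing utility takes the most recent observed utility; a
  missing period cost takes the most recent observed same-category period
  cost, with the baseline 10-week cost standing in for the first
  follow-up period. Trial baselines typically record healthcare cost
  only, so the generator also emits a (heavily zero-inflated) baseline
  social-care cost to give the social column something to carry; absent
  that column, zero is carried.
- **MICE**: chained equations with Bayesian draws — for a continuous
  variable, σ² from a scaled inverse-chi-square at the residual degrees
  of freedom, coefficients from their normal sampling distribution, then
  a noise-added prediction; for a binary variable, a logistic-coefficient
  draw. Defaults m = 5, 10 cycles, predictors (arm, sex, age, baseline
  utility, baseline cost); all are configurable. A degenerate model falls
  back to a marginal mean/mode draw with a warning. Observed cells are
  never modified, which the tests assert bit-for-bit.

Scalar estimates pool by Rubin's rules (total variance = within +
(1 + 1/m)·between, with Rubin's degrees of freedom). For the CEA itself
no standard combination rule exists; the package bootstraps within each
completed dataset and averages the m acceptability curves pointwise,
taking the ICER from the pooled mean differences. The alternative
(stacking completed datasets before bootstrapping) underweights
between-imputation uncertainty and was rejected.

## The synthetic trial generator

The generator exists so that every stage has realistic, seed-reproducible
input with known truth. What it emulates:

- **Arms and schedule**: 64/66 participants, EQ-5D at weeks 0/10/20.
- **Utilities**: a latent Gaussian AR(1) per participant
  (autocorrelation 0.6 by default), scaled to per-arm per-assessment
  means (0.70, 0.66, 0.74 intervention; 0.65, 0.66, 0.62 control; SD
  0.25) and censored at the EQ-5D bounds [−0.594, 1.00]. Trial reports
  give only cross-sectional summaries, so the serial correlation is a
  fixture choice, not an estimate; censoring shifts the realised means by
  under 0.02 at these SDs, a distortion accepted in exchange for hard
  bound preservation.
- **Resource-use counts** per item and 10-week period, with family
  chosen from the reported mean/SD pattern: negative binomial where the
  variance exceeds the mean (GP surgery visits, outpatient appointments;
  size parameter solved from mean and SD), Poisson for thin rare contacts,
  and zero-inflated Poisson for social-care items whose use concentrates
  in a few heavy users (a structural per-participant user indicator, then
  Poisson counts). Dispersions and zero masses are fixture choices
  derived once from the published summaries.
- **Costs**: log-normal baseline healthcare cost (mean £320, SD £400
  across the randomised cohort — between the reported completer and
  non-completer means) and log-normal medication costs per arm; both
  nonnegative and right-skewed.
- **Deaths**: per-arm probability 0.02, death week uniform on (0, 20].
- **Attrition**: a logistic dropout model on male sex and baseline cost
  only — never arm, never outcomes — so missingness is MAR given observed
  covariates by construction, matching a trial whose non-completers were
  more often male with higher pre-trial costs and whose missingness did
  not differ by arm. Coefficients (intercept −2.4, male +0.9, +0.003 per
  pound of baseline cost) give roughly 28% overall dropout. Dropouts lose
  follow-up data from week 10 or week 20 with equal probability.

What it does *not* emulate: clinical events (falls, balance scores),
geography (travel distances are drawn directly, calibrated to a ~£20 mean
return-mileage cost), within-person correlation between resource use and
utility (items are drawn independently given arm), and seasonal or
learning effects. Passing tests therefore show the *pipeline* is correct
under the stated data-generating assumptions, not that those assumptions
hold in any real cohort.

### The moment-matched reference cohort

Participant-level trial data behind published arm summaries are typically
unavailable. `ce_reference_cohort()` builds a synthetic stand-in: a
complete-case cohort (48/45) is generated and pushed through the costing
and QALY pipeline, then each arm's costs and QALYs are affinely rescaled
so the *sample* means and SDs equal published complete-case summaries
(healthcare costs 1198 (1192) vs 1320 (1676); combined costs 1444 (1953)
vs 1479 (1982); QALYs 0.40 (0.13) vs 0.37 (0.12)). The affine map
preserves the draws' shape — skewness, ranks, cross-correlations — while
pinning the moments, so bootstrap uncertainty remains genuine. Sample
(not population) matching is deliberate: with ΔC ≈ −£122 against a
sampling SE near £300, population-level calibration would leave even the
sign of a particular realisation to chance, which is not a useful
replication fixture. The two cost perspectives are calibrated
independently to their own published rows because the printed SDs embed
an unpublished correlation between healthcare and social-care costs; the
combined column is therefore not the sum of a healthcare and a social
column. The QALY column reproduces the published summary scale, which is
not recoverable from the published utility means under any common
trapezoid convention (those give ≈ 0.265 at 52 weeks/year, versus the
published 0.40); the calibration sidesteps that unresolvable discrepancy
rather than chasing it.

## Problem sizes and runtime choices

The test suite's simulation scales are chosen to give stable Monte-Carlo
verdicts in tens of seconds on one core: 200 cohorts for the
law-of-large-numbers check on generated contact rates, 500 replicate
cohorts for the attrition-mechanism check, 500 simulated trials at
B = 500 for bootstrap coverage (verdict band 0.90–0.98 for a nominal 95%
interval), B = 2000 against the closed-form bivariate-normal CEAC oracle,
and 100–200 seeds for the imputation recovery checks at m = 5. The
acceptance script uses B = 1000 bootstrap replications, matching common
practice for trial CEAs.

## Known limitations

- The CEAC convention is frequentist-bootstrap; no Bayesian posterior,
  Fieller ICER intervals, or value-of-information measures.
- LOCF for period costs is inherently ambiguous; the carried-period rule
  here is one documented choice.
- The MICE implementation covers continuous and binary variables with
  linear/logistic draws only — no predictive mean matching, no
  categorical-variable models, and no MNAR sensitivity.
- The generator draws resource items independently given arm; real
  utilisation is correlated across items and with utility (sicker
  participants cost more and score lower), which mildly affects joint
  quantities such as the CEAC's spread.
- Single-trial scope: no meta-analytic or long-term decision modelling.
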