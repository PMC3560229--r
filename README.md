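# trialcea

Within-trial cost-utility analysis in R: micro-costing, QALYs from EQ-5D,
bias-corrected bootstrap uncertainty, and cost-effectiveness acceptability
curves.

## What it is for

Economic evaluations run alongside randomised trials ask whether an
intervention is worth paying for: they compare the *joint* difference in
costs and health outcome between arms, not either alone. `trialcea`
implements that workflow end to end for a two-arm trial with scheduled
EQ-5D assessments and routinely collected health and social care resource
use — the design of a UK falls-prevention exercise trial in people with
Parkinson's (64 intervention / 66 control, assessments at weeks 0, 10 and
20), whose published arm-level summaries the package's defaults emulate.

The pieces, each usable on its own:

- **Unit-cost tariff** (`default_tariff()`, `derive_unit_cost()`): 2008/9
  UK prices for primary-care, hospital and social-care contacts, each
  stored with the derivation it came from (e.g. an acute bed day is
  £205 × 1.04 = £213.20; a residential-care day is a £958 short-term
  resident week / 7 = £136.86) and audited on construction.
- **Costing** (`cost_resource_use()`, `cost_intervention()`,
  `participant_travel_cost()`): applies the tariff to long-format
  resource-use records, held internally in integer pence so category and
  total sums are conserved exactly; micro-costs the group-exercise
  intervention from venue, therapist time, travel and equipment.
- **QALYs** (`qaly_auc()`): area under the piecewise-linear EQ-5D utility
  curve, utilities in [−0.594, 1.00], with deaths registered as zero
  utility from the assessment period in which they occur. QALYs are the
  dot product of utilities with explicit trapezoid weights
  (`qaly_weights()`).
- **Between-arm contrasts** (`mean_difference()`, `bootstrap_bc_ci()`,
  `poisson_rate_ratio()`, `relative_risk()`,
  `ols_adjusted_difference()`): Welch t-tests on mean costs,
  bias-corrected (BC) percentile bootstrap intervals from stratified
  within-arm resampling, closed-form Poisson rate ratios and Katz
  relative risks with Wald log-scale intervals, "not calculable" as a
  first-class result when a zero count blocks the interval.
- **Cost-effectiveness layer** (`icer()`, `nmb()`, `bootstrap_joint()`,
  `ceac()`, `ce_plane_summary()`, `run_cea()`): the incremental
  cost-effectiveness ratio ICER = ΔC/ΔE with dominance classification on
  the CE plane; net monetary benefit NMB(λ) = λ·ΔE − ΔC; the bootstrap of
  the joint (ΔC, ΔE) distribution; and the cost-effectiveness
  acceptability curve, P(NMB(λ) > 0) over ceiling ratios λ from £0 to
  £100,000 per QALY, with the decision read at the £20,000 threshold.
- **Missing data** (`complete_case_filter()`, `locf_impute()`,
  `mice_impute()`, `pool_estimates()`, `cea_imputed()`): complete-case
  selection with a missing-vs-available baseline comparison table,
  last-value-carried-forward, chained-equations multiple imputation, and
  Rubin's rules.
- **Synthetic trial generator** (`cohort_config()`, `generate_cohort()`,
  `apply_attrition()`): seed-reproducible datasets with serially
  correlated truncated utilities, overdispersed and zero-inflated
  resource-use counts, log-normal costs, deaths, and a logistic
  missing-at-random attrition mechanism driven by sex and baseline cost —
  so the whole pipeline is testable without any participant data.

## Worked example

```r
library(trialcea)

# 1. what did delivering the intervention cost?
cost_intervention(448, 3900, 335, 200, n_randomised = 64)
#> Intervention delivery cost: GBP 4,883
#>   components: venue=448, staff_time=3900, staff_travel=335, equipment=200
#>   per randomised participant: GBP 76
#>   scenario at group size 6 : GBP 3419.56 total, GBP 53 per participant

# 2. a QALY from a 20-week utility trajectory
qaly_auc(c(0, 10, 20), c(0.70, 0.66, 0.74))$qalys
#> [1] 0.2653846

# 3. did hospitalisation rates differ? (3 events in 48 vs 15 in 45)
poisson_rate_ratio(3, 48, 15, 45)
#> 0.188 (95% CI 0.054 to 0.648), p = 0.00813  [Poisson rate ratio]

# 4. the joint cost-effectiveness analysis, on a synthetic cohort whose
#    arm-level means and SDs match the published complete-case summaries
ref <- ce_reference_cohort(seed = 3)
run_cea(data.frame(arm = ref$arm, cost = ref$cost_healthcare,
                   qaly = ref$qaly), B = 1000, seed = 5)
#> Cost-effectiveness analysis (healthcare perspective, B = 1000)
#>   incremental cost (GBP): -122 (95% CI -710.786 to 474.986)  [bootstrap BC]
#>   incremental QALYs:      0.03 (95% CI -0.0222 to 0.0812)  [bootstrap BC]
#>   ICER: GBP -4,067 per QALY | dominant ( SE quadrant )
#>   P(cost-effective at GBP 20000/QALY) = 0.863
```

Reading the output: the intervention arm cost £122 less per participant and
gained 0.03 QALYs on average — both differences statistically
indistinguishable from zero (the bootstrap intervals span it) — so the
point estimate sits in the dominant (cheaper *and* more effective)
quadrant, and about 86% of bootstrap replicates have positive net monetary
benefit at a willingness to pay of £20,000 per QALY. Wide intervals with a
high probability of cost-effectiveness is exactly the situation
acceptability curves exist to communicate.

A full synthetic trial, with attrition and imputation:

```r
cfg <- cohort_config(seed = 42)          # 64/66 arms, week 0/10/20 EQ-5D
dat <- apply_attrition(generate_cohort(cfg), cfg)
tab <- analysis_table(dat)               # wide table, costed per period
cc  <- complete_case_filter(tab)         # subset + Table-2-style report
imp <- mice_impute(tab, m = 5, seed = 7) # chained-equations sensitivity
```

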