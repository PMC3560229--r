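Package: trialcea
Title: Within-Trial Cost-Utility Analysis with Bootstrap Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-based economic evaluation: unit-cost tariffs and
    micro-costing of resource use and intervention delivery, quality-adjusted
    life years (QALYs) from EQ-5D utility trajectories by the area-under-the-
    curve method with death handling, between-arm contrasts (Welch t-tests,
    baseline-adjusted least squares, Poisson rate ratios, relative risks),
    bias-corrected non-parametric bootstrap confidence intervals, incremental
    cost-effectiveness ratios with dominance classification, net monetary
    benefit and cost-effectiveness acceptability curves, complete-case and
    imputation-based (last value carried forward; chained equations with
    Rubin pooling) sensitivity analyses, and a seed-reproducible synthetic
    two-arm trial generator with a covariate-driven attrition mechanism for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
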