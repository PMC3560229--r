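test_that("complete-case selection counts and reports correctly", {
  tab <- small_complete_table(61)
  cc <- complete_case_filter(tab)
  expect_equal(cc$n_missing, 0)
  expect_equal(nrow(cc$complete), nrow(tab))
  # flag 37 of 130 as missing: the published attrition pattern
  cfg <- cohort_config(seed = 62,
                       death_prob = c(intervention = 0, control = 0))
  full <- analysis_table(generate_cohort(cfg))
  full$u20[1:37] <- NA
  cc2 <- complete_case_filter(full)
  expect_equal(cc2$n_available, 93)
  expect_equal(cc2$n_missing, 37)
  expect_true(all(c("baseline_cost", "male") %in%
                    cc2$report$characteristic))
})

test_that("male-driven attrition is flagged by the baseline comparison", {
  hits <- vapply(1:30, function(i) {
    cfg <- cohort_config(missing_model = c(intercept = -1.5, male = 2.5,
                                           baseline_cost = 0),
                         count_models = silent_count_models(),
                         death_prob = c(intervention = 0, control = 0),
                         seed = 8000 + i)
    tab <- analysis_table(apply_attrition(generate_cohort(cfg), cfg))
    rep <- complete_case_filter(tab)$report
    p <- rep$p[rep$characteristic == "male"]
    !is.na(p) && p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("deaths are resolved, not treated as missing", {
  tab <- small_complete_table(63)
  tab$death_week[1] <- 5
  tab$u10[1] <- NA
  tab$u20[1] <- NA
  cc <- complete_case_filter(tab)
  expect_equal(cc$n_missing, 0)
})

test_that("last value carried forward follows the carry rules", {
  tab <- small_complete_table(64)
  i <- c(2, 5)
  tab$u10[i[1]] <- NA; tab$u20[i] <- NA
  tab$hc_cost_1[i[1]] <- NA; tab$hc_cost_2[i[1]] <- NA
  tab$soc_cost_1[i[1]] <- NA; tab$soc_cost_2[i[1]] <- NA
  imp <- locf_impute(tab)
  expect_equal(imp$m, 1L)
  out <- imp$datasets[[1]]
  # utilities carry the most recent observed value
  expect_equal(out$u10[i[1]], out$u0[i[1]])
  expect_equal(out$u20[i[1]], out$u0[i[1]])
  expect_equal(out$u20[i[2]], out$u10[i[2]])
  # all follow-up healthcare missing: both periods carry baseline,
  # so the imputed follow-up total is twice the baseline period cost
  expect_equal(out$hc_cost_1[i[1]] + out$hc_cost_2[i[1]],
               2 * tab$baseline_cost[i[1]])
  expect_equal(out$soc_cost_1[i[1]], tab$baseline_social_cost[i[1]])
  # nothing missing elsewhere: identity
  untouched <- setdiff(seq_len(nrow(tab)), i)
  expect_identical(out[untouched, ], tab[untouched, ])
  # error path: unobserved baseline
  bad <- tab; bad$u0[1] <- NA
  expect_error(locf_impute(bad), "baseline")
})

test_that("imputation never modifies observed cells", {
  tab <- small_complete_table(65)
  mis <- sample(nrow(tab), 15)
  tab$u20[mis] <- NA
  tab$hc_cost_2[mis[1:8]] <- NA
  for (imp in list(locf_impute(tab),
                   mice_impute(tab, m = 3, iterations = 3, seed = 66))) {
    for (d in imp$datasets) {
      expect_false(anyNA(d$u20))
      obs <- !is.na(tab$u20)
      expect_identical(d$u20[obs], tab$u20[obs])
      obs_c <- !is.na(tab$hc_cost_2)
      expect_identical(d$hc_cost_2[obs_c], tab$hc_cost_2[obs_c])
      expect_identical(d$u0, tab$u0)
    }
  }
})

test_that("chained equations return identical copies when nothing is missing", {
  tab <- small_complete_table(67)
  imp <- mice_impute(tab, m = 3, iterations = 2, seed = 68)
  expect_equal(imp$m, 3L)
  for (d in imp$datasets) expect_identical(d, tab)
})

test_that("chained equations recover the mean under MAR", {
  # known truth: y = mu + 0.5 x + e, missingness depends only on observed x
  mu <- 10
  pooled <- vapply(1:200, function(s) {
    set.seed(9000 + s)
    n <- 150
    x <- rnorm(n)
    y <- mu + 0.5 * x + rnorm(n)
    tab <- data.frame(x = x, y = ifelse(rbinom(n, 1, plogis(-1 + 1.5 * x)),
                                        NA, y))
    imp <- mice_impute(tab, m = 5, iterations = 5, seed = s,
                       predictors = "x", impute_vars = "y")
    mean(vapply(imp$datasets, function(d) mean(d$y), numeric(1)))
  }, numeric(1))
  se <- sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - mu), 3 * se)
})

test_that("MCAR deletion leaves the imputed estimate unbiased", {
  diffs <- vapply(1:100, function(s) {
    set.seed(9500 + s)
    tab <- small_complete_table(9500 + s)
    full_mean <- mean(tab$hc_cost_1)
    tab$hc_cost_1[rbinom(nrow(tab), 1, 0.2) == 1] <- NA
    imp <- mice_impute(tab, m = 5, iterations = 5, seed = s)
    mean(vapply(imp$datasets, function(d) mean(d$hc_cost_1),
                numeric(1))) - full_mean
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("Rubin pooling matches the hand formula", {
  # identical estimates: between-variance vanishes
  p0 <- pool_estimates(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(p0$estimate, 2)
  expect_equal(p0$variance, 0.5)
  expect_equal(p0$between, 0)
  # hand-computed three-imputation case
  p <- pool_estimates(c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_equal(p$estimate, 2)
  expect_equal(p$within, 0.5)
  expect_equal(p$between, 1)
  expect_equal(p$variance, 0.5 + (1 + 1 / 3) * 1)
  expect_error(pool_estimates(1, 0.5), "m >= 2")
})

test_that("imputed-data CEA keeps endpoints and qualitative conclusions", {
  ref <- ce_reference_cohort(seed = 70)
  tab <- data.frame(id = ref$id, arm = ref$arm, male = rbinom(93, 1, 0.5),
                    age = rnorm(93, 71, 8), u0 = rnorm(93, 0.67, 0.2),
                    baseline_cost = rlnorm(93, 5.3, 1),
                    cost = ref$cost_healthcare, qaly = ref$qaly)
  cc <- run_cea(tab[, c("arm", "cost", "qaly")], B = 500, seed = 71)
  # superimpose MAR missingness driven by observed covariates
  set.seed(72)
  mis <- rbinom(93, 1, plogis(-2 + tab$male)) == 1
  tab$cost[mis] <- NA
  tab$qaly[mis] <- NA
  imp <- mice_impute(tab, m = 5, iterations = 5, seed = 73,
                     impute_vars = c("cost", "qaly"))
  res <- cea_imputed(imp, function(d) d[, c("arm", "cost", "qaly")],
                     B = 500, seed = 74)
  # endpoint identity survives pointwise averaging
  p0 <- mean(vapply(res$per_imputation, function(r)
    mean(r$replicates$replicates$delta_cost < 0), numeric(1)))
  expect_equal(res$ceac$p_intervention[res$ceac$lambda == 0], p0)
  # conclusions agree with the complete-data analysis
  expect_equal(sign(res$delta_qaly), sign(cc$replicates$delta_qaly))
  # imputation adds between-imputation uncertainty, flattening the curve
  # toward one half, so agreement is qualitative rather than tight
  expect_lt(abs(res$ceac$p_intervention[res$ceac$lambda == 20000] -
                  cc$plane$p_cost_effective), 0.3)
  expect_gt(res$ceac$p_intervention[res$ceac$lambda == 20000], 0.5)
  expect_equal(res$icer$classification, "dominant")
})
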