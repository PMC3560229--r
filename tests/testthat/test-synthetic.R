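test_that("identical configs reproduce identical datasets; seeds differ", {
  cfg <- small_config(31)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1, d2)
  d3 <- generate_cohort(small_config(32))
  expect_false(identical(d1$utilities$utility, d3$utilities$utility))
})

test_that("zero utility noise collapses to the arm means", {
  cfg <- small_config(33, utility_sd = 0)
  d <- generate_cohort(cfg)
  tab <- analysis_table(d)
  for (a in c("intervention", "control")) {
    sel <- tab$arm == a
    expect_true(all(tab$u0[sel] == cfg$utility_means[[a]][1]))
    expect_true(all(tab$u10[sel] == cfg$utility_means[[a]][2]))
    expect_true(all(tab$u20[sel] == cfg$utility_means[[a]][3]))
  }
})

test_that("zero rates generate no records; utilities stay inside the bounds", {
  cfg <- small_config(34, count_models = silent_count_models())
  d <- generate_cohort(cfg)
  expect_false(any(d$resource_use$category %in% c("primary", "acute",
                                                  "social")))
  u <- d$utilities$utility
  expect_true(all(is.na(u) | (u >= EQ5D_BOUNDS[1] & u <= EQ5D_BOUNDS[2])))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(utility_sd = -1), "utility_sd")
  expect_error(cohort_config(utility_autocorrelation = 1), "autocorrelation")
  expect_error(cohort_config(death_prob = c(intervention = 1.2,
                                            control = 0)), "death_prob")
  expect_error(cohort_config(utility_means = list(
    intervention = c(0.7, 0.7, 1.5), control = c(0.6, 0.6, 0.6))),
    "utility_means")
  cm <- default_count_models()
  cm$rate_control[1] <- -2
  expect_error(cohort_config(count_models = cm), "count_models")
})

test_that("simulated GP contact rates concentrate on the configured means", {
  # law of large numbers across Monte-Carlo cohorts at the published rates
  n_coh <- 200
  means <- vapply(seq_len(n_coh), function(i) {
    cfg <- cohort_config(n_per_arm = c(intervention = 48, control = 45),
                         death_prob = c(intervention = 0, control = 0),
                         seed = 5000 + i)
    d <- generate_cohort(cfg)
    r <- d$resource_use
    gp <- r[r$item == "gp_surgery", ]
    arm <- d$participants$arm[match(gp$id, d$participants$id)]
    c(sum(gp$amount[arm == "intervention"]) / 48,
      sum(gp$amount[arm == "control"]) / 45)
  }, numeric(2))
  # SE of a cohort arm mean ~ sd/sqrt(n); of the grand mean, /sqrt(n_coh)
  se_i <- 3.05 / sqrt(48) / sqrt(n_coh)
  se_c <- 2.58 / sqrt(45) / sqrt(n_coh)
  expect_lt(abs(mean(means[1, ]) - 2.19), 3 * se_i)
  expect_lt(abs(mean(means[2, ]) - 1.96), 3 * se_c)
})

test_that("attrition follows the configured logistic mechanism", {
  # flat mechanism: observed missingness near the intercept probability
  cfg <- small_config(36, n_per_arm = c(intervention = 300, control = 300),
                      missing_model = c(intercept = qlogis(0.3), male = 0,
                                        baseline_cost = 0))
  d <- apply_attrition(generate_cohort(cfg), cfg)
  frac <- mean(!is.na(d$participants$missing_from_week))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 600))
  # essentially impossible dropout: nothing missing
  cfg0 <- small_config(37, missing_model = c(intercept = -40, male = 0,
                                             baseline_cost = 0))
  d0 <- apply_attrition(generate_cohort(cfg0), cfg0)
  expect_true(all(is.na(d0$participants$missing_from_week)))
  expect_false(anyNA(analysis_table(d0)$u20))
})

test_that("a positive male coefficient drives excess male missingness", {
  excess <- vapply(1:500, function(i) {
    cfg <- cohort_config(missing_model = c(intercept = -1.5, male = 2,
                                           baseline_cost = 0),
                         count_models = silent_count_models(),
                         death_prob = c(intervention = 0, control = 0),
                         seed = 7000 + i)
    p <- apply_attrition(generate_cohort(cfg), cfg)$participants
    miss <- !is.na(p$missing_from_week)
    mean(miss[p$male == 1]) > mean(miss[p$male == 0])
  }, logical(1))
  expect_gt(mean(excess), 0.95)
})

test_that("attrition cuts follow-up data consistently across tables", {
  cfg <- small_config(38)
  d <- apply_attrition(generate_cohort(cfg), cfg)
  p <- d$participants
  cut10 <- p$id[!is.na(p$missing_from_week) & p$missing_from_week == 10]
  cut20 <- p$id[!is.na(p$missing_from_week) & p$missing_from_week == 20]
  u10 <- d$utilities[d$utilities$week == 10, ]
  u20 <- d$utilities[d$utilities$week == 20, ]
  expect_true(all(is.na(u10$utility[u10$id %in% cut10])))
  expect_true(all(is.na(u20$utility[u20$id %in% c(cut10, cut20)])))
  expect_false(any(d$resource_use$id %in% cut10))
  expect_false(any(d$resource_use$id %in% cut20 &
                     d$resource_use$period == "weeks_10_20"))
  # baseline assessments are never removed by attrition
  u0 <- d$utilities[d$utilities$week == 0, ]
  expect_false(anyNA(u0$utility))
})

test_that("written CSV inputs round-trip the generated data", {
  d <- generate_cohort(small_config(39))
  dir <- withr::local_tempdir()
  write_trial_csvs(d, dir)
  expect_true(all(file.exists(file.path(dir, c("participants.csv",
                                               "utilities.csv",
                                               "resource_use.csv",
                                               "config.yaml")))))
  u <- read.csv(file.path(dir, "utilities.csv"))
  expect_equal(u$utility, d$utilities$utility)
  r <- read.csv(file.path(dir, "resource_use.csv"))
  expect_equal(nrow(r), nrow(d$resource_use))
  expect_true(all(r$id %in% d$participants$id))
})
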