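# Seed-reproducible synthetic two-arm trial generator. Emulates the data
# structure the analysis consumes: baseline covariates, EQ-5D utility
# trajectories with serial correlation and deaths, zero-inflated /
# overdispersed resource-use counts, pre-priced medication costs, and a
# covariate-driven (missing-at-random) attrition mechanism that never reads
# arm or outcomes.

#' Default resource-use count models
#'
#' One row per costed item: distributional family (`poisson`,
#' `negative_binomial`, `zero_inflated_poisson`), event rate per participant
#' per 20 weeks in each arm, negative-binomial size and structural-zero
#' mass where the family needs them. Defaults reflect a falls-prone
#' Parkinson's cohort: frequent GP and outpatient contact (overdispersed),
#' rare hospitalisations, and heavily zero-inflated social-care use
#' concentrated in a few high users.
#'
#' @return data.frame of per-item count models.
#' @export
default_count_models <- function() {
  cm <- read.csv(text = "
category,item,family,rate_intervention,rate_control,size_intervention,size_control,zero_intervention,zero_control
primary,gp_surgery,negative_binomial,2.19,1.96,0.67,0.82,NA,NA
primary,gp_home_visit,poisson,0.08,0.09,NA,NA,NA,NA
primary,practice_nurse,negative_binomial,0.83,0.84,1.28,0.60,NA,NA
primary,community_nurse,zero_inflated_poisson,0.04,0.23,NA,NA,0.98,0.90
acute,hospitalisation,poisson,0.06,0.33,NA,NA,NA,NA
acute,inpatient_bed_day,zero_inflated_poisson,0.50,1.51,NA,NA,0.95,0.80
acute,day_admission,poisson,0.02,0.11,NA,NA,NA,NA
acute,ae_attendance,poisson,0.10,0.16,NA,NA,NA,NA
acute,outpatient_followup,negative_binomial,2.25,2.69,2.17,1.42,NA,NA
acute,pdns_appointment,poisson,0.00,0.02,NA,NA,NA,NA
social,care_assessment,poisson,0.17,0.04,NA,NA,NA,NA
social,home_care_hour,zero_inflated_poisson,9.15,2.00,NA,NA,0.96,0.98
social,day_care_hour,zero_inflated_poisson,0.42,0.00,NA,NA,0.98,1.00
social,residential_care_day,zero_inflated_poisson,0.00,0.44,NA,NA,1.00,0.98
social,nursing_care_day,zero_inflated_poisson,0.00,0.42,NA,NA,1.00,0.98
", stringsAsFactors = FALSE, strip.white = TRUE)
  cm
}

lognormal_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for the synthetic trial generator
#'
#' Defaults mirror the structure of a 130-participant falls-prevention
#' exercise trial: arms of 64/66, EQ-5D assessments at weeks 0/10/20 with
#' arm-by-assessment means of (0.70, 0.66, 0.74) vs (0.65, 0.66, 0.62),
#' resource-use rates per item from [default_count_models()], heavily
#' right-skewed (log-normal) baseline and medication costs, and a logistic
#' attrition model on male sex and baseline healthcare cost calibrated to
#' drop roughly 28% of participants.
#'
#' @param n_per_arm named integer vector `c(intervention =, control =)`.
#' @param assessment_weeks scheduled EQ-5D assessment weeks (first must
#'   be 0).
#' @param utility_means list with per-arm numeric vectors of EQ-5D means,
#'   one per assessment, inside the index range \[-0.594, 1\].
#' @param utility_sd cross-sectional utility standard deviation.
#' @param utility_autocorrelation latent serial correlation in \[0, 1).
#' @param count_models data.frame as [default_count_models()].
#' @param binary_med_probs named list of per-arm probabilities of use for
#'   each medication class.
#' @param medication_cost per-arm mean/sd (pounds per 20 weeks) of the
#'   log-normal medication cost.
#' @param death_prob per-arm probability of death during follow-up.
#' @param missing_model logistic attrition coefficients
#'   `c(intercept =, male =, baseline_cost =)`; arm and outcomes are never
#'   predictors, so attrition is missing-at-random given (sex, baseline
#'   cost).
#' @param male_prob probability male.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param years_dx_mean,years_dx_sd disease duration (gamma, years).
#' @param hy_mean,hy_sd Hoehn & Yahr stage (rounded normal, clamped 1-5).
#' @param living_probs named probabilities over living arrangements.
#' @param comorbidity_probs named probabilities of comorbidities.
#' @param baseline_cost_mean,baseline_cost_sd 10-week pre-trial healthcare
#'   cost (log-normal, pounds).
#' @param baseline_social_zero,baseline_social_mean,baseline_social_sd
#'   zero-mass and log-normal body of the 10-week pre-trial social-care
#'   cost.
#' @param travel list: `distance_mean`, `distance_sd` (one-way miles),
#'   `sessions`, `rate` (pounds/mile) for intervention participants.
#' @param seed integer seed; identical (config, seed) reproduces the
#'   dataset exactly.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_arm = c(intervention = 64, control = 66),
    assessment_weeks = c(0, 10, 20),
    utility_means = list(intervention = c(0.70, 0.66, 0.74),
                         control = c(0.65, 0.66, 0.62)),
    utility_sd = 0.25,
    utility_autocorrelation = 0.6,
    count_models = default_count_models(),
    binary_med_probs = list(lct = c(0.91, 0.93), ga = c(0.02, 0.07),
                            ac = c(0.005, 0.02), cti = c(0.02, 0.07),
                            dra = c(0.42, 0.40), maoi = c(0.09, 0.12)),
    medication_cost = list(mean = c(intervention = 836, control = 707),
                           sd = c(intervention = 994, control = 812)),
    death_prob = c(intervention = 0.02, control = 0.02),
    missing_model = c(intercept = -2.4, male = 0.9, baseline_cost = 0.003),
    male_prob = 0.57,
    age_mean = 71, age_sd = 8.5,
    years_dx_mean = 8.7, years_dx_sd = 6.4,
    hy_mean = 2.5, hy_sd = 0.9,
    living_probs = c(alone = 0.25, partner = 0.70, family = 0.03,
                     residential = 0.02),
    comorbidity_probs = c(orthopaedic = 0.35, cardiac = 0.35),
    baseline_cost_mean = 320, baseline_cost_sd = 400,
    baseline_social_zero = 0.9, baseline_social_mean = 200,
    baseline_social_sd = 250,
    travel = list(distance_mean = 2.5, distance_sd = 0.25, sessions = 10,
                  rate = 0.40),
    seed = 1L) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  check_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid configuration: '", field, "' must lie in [0, 1]")
    }
  }
  if (any(cfg$n_per_arm < 1) ||
      !setequal(names(cfg$n_per_arm), c("intervention", "control"))) {
    stop("invalid configuration: 'n_per_arm' must be positive and named ",
         "intervention/control")
  }
  if (cfg$assessment_weeks[1] != 0 || any(diff(cfg$assessment_weeks) <= 0)) {
    stop("invalid configuration: 'assessment_weeks' must start at 0 and ",
         "increase")
  }
  um <- unlist(cfg$utility_means)
  if (any(um < EQ5D_BOUNDS[1]) || any(um > EQ5D_BOUNDS[2])) {
    stop("invalid configuration: 'utility_means' outside the EQ-5D range [",
         EQ5D_BOUNDS[1], ", ", EQ5D_BOUNDS[2], "]")
  }
  if (any(lengths(cfg$utility_means) != length(cfg$assessment_weeks))) {
    stop("invalid configuration: 'utility_means' must give one mean per ",
         "assessment per arm")
  }
  if (cfg$utility_sd < 0) {
    stop("invalid configuration: 'utility_sd' must be nonnegative")
  }
  if (cfg$utility_autocorrelation < 0 || cfg$utility_autocorrelation >= 1) {
    stop("invalid configuration: 'utility_autocorrelation' must be in [0, 1)")
  }
  cm <- cfg$count_models
  if (any(cm$rate_intervention < 0) || any(cm$rate_control < 0)) {
    stop("invalid configuration: 'count_models' rates must be nonnegative")
  }
  check_prob(stats::na.omit(c(cm$zero_intervention, cm$zero_control)),
             "count_models zero mass")
  check_prob(unlist(cfg$binary_med_probs), "binary_med_probs")
  check_prob(cfg$death_prob, "death_prob")
  check_prob(cfg$male_prob, "male_prob")
  check_prob(cfg$living_probs, "living_probs")
  check_prob(cfg$comorbidity_probs, "comorbidity_probs")
  if (abs(sum(cfg$living_probs) - 1) > 1e-8) {
    stop("invalid configuration: 'living_probs' must sum to 1")
  }
  invisible(cfg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Latent Gaussian AR(1) per participant, scaled to the utility mean/sd and
# censored at the EQ-5D bounds ("truncated Gaussian copula" in design terms).
draw_utilities <- function(n, means, sd, rho) {
  k <- length(means)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (k > 1) {
    for (t in 2:k) z[, t] <- rho * z[, t - 1] + sqrt(1 - rho^2) * z[, t]
  }
  u <- sweep(z * sd, 2, means, `+`)
  clamp(u, EQ5D_BOUNDS[1], EQ5D_BOUNDS[2])
}

draw_counts <- function(n, family, rate, size = NA, zero = NA) {
  # rate is per 20 weeks; each of the two follow-up periods gets half
  per_period <- rate / 2
  draw_one <- function() {
    switch(family,
      poisson = stats::rpois(n, per_period),
      negative_binomial = stats::rnbinom(n, size = size / 2, mu = per_period),
      zero_inflated_poisson = stop("handled by caller"),
      stop("unknown count family '", family, "'"))
  }
  if (family == "zero_inflated_poisson") {
    if (zero >= 1 || rate == 0) {
      return(list(p1 = integer(n), p2 = integer(n)))
    }
    user <- stats::rbinom(n, 1, 1 - zero)  # structural: a user or not
    lambda <- rate / (1 - zero) / 2
    list(p1 = user * stats::rpois(n, lambda),
         p2 = user * stats::rpois(n, lambda))
  } else {
    list(p1 = draw_one(), p2 = draw_one())
  }
}

#' Generate a synthetic two-arm trial dataset
#'
#' @param config a [cohort_config()].
#' @return list of class `trial_dataset`: `participants` (one row per
#'   participant: arm, covariates, medication-class indicators, baseline
#'   costs, death and travel fields), `utilities` (long: id, week,
#'   utility; `NA` after death), `resource_use` (long records: id,
#'   category, item, amount, period), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arms <- c("intervention", "control")
  n <- sum(config$n_per_arm)
  arm <- rep(arms, times = config$n_per_arm[arms])
  id <- sprintf("P%03d", seq_len(n))
  is_int <- arm == "intervention"

  p <- data.frame(id = id, arm = arm, stringsAsFactors = FALSE)
  p$age <- round(stats::rnorm(n, config$age_mean, config$age_sd), 1)
  p$male <- stats::rbinom(n, 1, config$male_prob)
  shp <- (config$years_dx_mean / config$years_dx_sd)^2
  p$years_since_diagnosis <- round(
    stats::rgamma(n, shape = shp, rate = shp / config$years_dx_mean), 1)
  p$hoehn_yahr <- clamp(round(stats::rnorm(n, config$hy_mean, config$hy_sd)),
                        1, 5)
  p$living <- sample(names(config$living_probs), n, replace = TRUE,
                     prob = config$living_probs)
  for (cm in names(config$comorbidity_probs)) {
    p[[paste0("comorbid_", cm)]] <-
      stats::rbinom(n, 1, config$comorbidity_probs[[cm]])
  }
  for (med in names(config$binary_med_probs)) {
    pr <- config$binary_med_probs[[med]]
    p[[paste0("med_", med)]] <- stats::rbinom(n, 1, ifelse(is_int, pr[1],
                                                           pr[2]))
  }
  blp <- lognormal_params(config$baseline_cost_mean, config$baseline_cost_sd)
  p$baseline_cost <- round_penny(
    stats::rlnorm(n, blp$meanlog, blp$sdlog))
  bsp <- lognormal_params(config$baseline_social_mean,
                          config$baseline_social_sd)
  p$baseline_social_cost <- round_penny(
    stats::rbinom(n, 1, 1 - config$baseline_social_zero) *
      stats::rlnorm(n, bsp$meanlog, bsp$sdlog))
  dead <- stats::rbinom(n, 1, ifelse(is_int, config$death_prob[["intervention"]],
                                     config$death_prob[["control"]])) == 1
  horizon <- max(config$assessment_weeks)
  p$death_week <- ifelse(dead, stats::runif(n, 0, horizon), NA_real_)
  p$travel_distance <- ifelse(
    is_int,
    pmax(0, stats::rnorm(n, config$travel$distance_mean,
                         config$travel$distance_sd)),
    NA_real_)
  p$missing_from_week <- NA_real_

  # utilities: one long row per participant x scheduled assessment
  weeks <- config$assessment_weeks
  u <- matrix(NA_real_, n, length(weeks))
  for (a in arms) {
    sel <- arm == a
    u[sel, ] <- draw_utilities(sum(sel), config$utility_means[[a]],
                               config$utility_sd,
                               config$utility_autocorrelation)
  }
  for (j in seq_along(weeks)) {
    gone <- !is.na(p$death_week) & p$death_week <= weeks[j] & weeks[j] > 0
    u[gone, j] <- NA_real_
  }
  utilities <- data.frame(id = rep(id, times = length(weeks)),
                          week = rep(weeks, each = n),
                          utility = as.vector(u), stringsAsFactors = FALSE)

  # resource use per item and period
  rec <- list()
  add_records <- function(ids, category, item, amount, period) {
    keep <- amount > 0
    if (!any(keep)) return()
    rec[[length(rec) + 1L]] <<- data.frame(
      id = ids[keep], category = category, item = item,
      amount = amount[keep], period = period, stringsAsFactors = FALSE)
  }
  cmods <- config$count_models
  for (a in arms) {
    sel <- arm == a
    sfx <- if (a == "intervention") "intervention" else "control"
    for (i in seq_len(nrow(cmods))) {
      d <- draw_counts(sum(sel), cmods$family[i],
                       cmods[[paste0("rate_", sfx)]][i],
                       size = cmods[[paste0("size_", sfx)]][i],
                       zero = cmods[[paste0("zero_", sfx)]][i])
      add_records(id[sel], cmods$category[i], cmods$item[i], d$p1,
                  "weeks_0_10")
      add_records(id[sel], cmods$category[i], cmods$item[i], d$p2,
                  "weeks_10_20")
    }
    mcp <- lognormal_params(config$medication_cost$mean[[a]],
                            config$medication_cost$sd[[a]])
    med <- round_penny(stats::rlnorm(sum(sel), mcp$meanlog, mcp$sdlog))
    add_records(id[sel], "medication", "parkinsons_medication",
                round_penny(med / 2), "weeks_0_10")
    add_records(id[sel], "medication", "parkinsons_medication",
                round_penny(med / 2), "weeks_10_20")
  }
  resource_use <- if (length(rec)) do.call(rbind, rec) else
    data.frame(id = character(0), category = character(0),
               item = character(0), amount = numeric(0),
               period = character(0), stringsAsFactors = FALSE)
  resource_use <- resource_use[order(resource_use$id, resource_use$category,
                                     resource_use$item,
                                     resource_use$period), ]
  rownames(resource_use) <- NULL

  structure(list(participants = p, utilities = utilities,
                 resource_use = resource_use, config = config),
            class = "trial_dataset")
}

#' Apply the attrition mechanism
#'
#' Draws dropout from the configured logistic model on male sex and
#' baseline healthcare cost — never on arm or on outcome values, so the
#' mechanism is missing-at-random given those covariates. Dropouts lose
#' their follow-up data from week 10 or week 20 (equally likely): utilities
#' at and after that week are set missing and resource-use records in the
#' affected periods are removed, with `missing_from_week` recording the cut.
#'
#' @param dataset a `trial_dataset` from [generate_cohort()].
#' @param config the matching [cohort_config()].
#' @return the dataset with missingness applied (deterministic given the
#'   config seed).
#' @export
apply_attrition <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "trial_dataset"))
  p <- dataset$participants
  if (anyNA(p$male) || anyNA(p$baseline_cost)) {
    stop("sex and baseline_cost must be populated before attrition")
  }
  mm <- config$missing_model
  set.seed(config$seed + 1L)
  lp <- mm[["intercept"]] + mm[["male"]] * p$male +
    mm[["baseline_cost"]] * p$baseline_cost
  drop_flag <- stats::rbinom(nrow(p), 1, stats::plogis(lp)) == 1
  cut_week <- ifelse(drop_flag, sample(c(10, 20), nrow(p), replace = TRUE),
                     NA_real_)
  p$missing_from_week <- cut_week
  u <- dataset$utilities
  cut_for_row <- cut_week[match(u$id, p$id)]
  u$utility[!is.na(cut_for_row) & u$week >= cut_for_row & u$week > 0] <-
    NA_real_
  r <- dataset$resource_use
  cut_for_rec <- cut_week[match(r$id, p$id)]
  # a cut at week 10 removes both follow-up periods; at week 20 only the
  # second (a period counts as observed only if completed before the cut)
  keep <- is.na(cut_for_rec) |
    (r$period == "weeks_0_10" & cut_for_rec >= 20) |
    (r$period == "baseline")
  dataset$participants <- p
  dataset$utilities <- u
  dataset$resource_use <- r[keep, , drop = FALSE]
  rownames(dataset$resource_use) <- NULL
  dataset
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Synthetic trial dataset:", nrow(x$participants), "participants (",
      sum(x$participants$arm == "intervention"), "intervention /",
      sum(x$participants$arm == "control"), "control ),",
      nrow(x$resource_use), "resource-use records\n")
  invisible(x)
}

#' Write the analysis input files
#'
#' Writes `participants.csv`, `utilities.csv` (long: id, week, utility),
#' `resource_use.csv` (id, category, item, amount, period) and a
#' `config.yaml` echo of the generator configuration. Comma-separated,
#' UTF-8, header row.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_csvs <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$utilities, file.path(dir, "utilities.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$resource_use, file.path(dir, "resource_use.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  echo <- lapply(unclass(cfg), function(x) {
    if (is.data.frame(x)) lapply(x, function(col) unname(as.vector(col)))
    else x
  })
  yaml::write_yaml(echo, file.path(dir, "config.yaml"))
  invisible(dir)
}
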