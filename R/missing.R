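# Missing-data handling: complete-case selection with a missing-vs-available
# baseline comparison, last-value-carried-forward single imputation, multiple
# imputation by chained equations (Bayesian linear draws for continuous
# variables, logistic draws for binary), and Rubin's combination rules.

ANALYSIS_VARS <- c("u10", "u20", "hc_cost_1", "hc_cost_2",
                   "soc_cost_1", "soc_cost_2")

# NA in a utility column is "resolved" (not analysis-blocking) if the
# participant died at or before that assessment week.
death_resolved <- function(tab, col, week) {
  if (!"death_week" %in% names(tab)) return(rep(FALSE, nrow(tab)))
  is.na(tab[[col]]) & !is.na(tab$death_week) & tab$death_week <= week
}

analysis_complete <- function(tab) {
  miss <- matrix(FALSE, nrow(tab), 0)
  for (v in intersect(ANALYSIS_VARS, names(tab))) {
    m <- is.na(tab[[v]])
    if (v == "u10") m <- m & !death_resolved(tab, v, 10)
    if (v == "u20") m <- m & !death_resolved(tab, v, 20)
    miss <- cbind(miss, m)
  }
  rowSums(miss) == 0
}

#' Complete-case selection with a baseline comparison report
#'
#' Retains participants complete on both total costs and QALYs (deaths are
#' resolved by the zero-utility rule, not treated as missing) and compares
#' the baseline characteristics of the available and missing groups:
#' two-sample t-tests for continuous characteristics, chi-square tests for
#' categorical (Fisher's exact test when any expected cell count falls
#' below 5).
#'
#' @param tab wide analysis table (one row per participant), as produced by
#'   [analysis_table()].
#' @param continuous,categorical names of baseline columns to compare;
#'   defaults cover age, disease duration, disease stage, baseline utility
#'   and baseline healthcare cost, and sex, living arrangements, medication
#'   classes and comorbidities where present.
#' @return list of class `complete_case_result`: `complete` (the subset),
#'   `n_available`, `n_missing`, and `report` (data.frame: characteristic,
#'   available/missing summaries, test, p-value).
#' @export
complete_case_filter <- function(tab,
    continuous = c("age", "years_since_diagnosis", "hoehn_yahr", "u0",
                   "baseline_cost"),
    categorical = c("male", "living", "med_lct", "med_dra", "med_maoi",
                    "comorbid_orthopaedic", "comorbid_cardiac")) {
  complete <- analysis_complete(tab)
  continuous <- intersect(continuous, names(tab))
  categorical <- intersect(categorical, names(tab))
  rows <- list()
  for (v in continuous) {
    a <- tab[[v]][complete]; m <- tab[[v]][!complete]
    p <- if (length(m) >= 2 && length(a) >= 2 &&
             stats::sd(c(a, m), na.rm = TRUE) > 0) {
      stats::t.test(a, m)$p.value
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = v, type = "continuous",
      available = sprintf("%.2f (%.2f)", mean(a, na.rm = TRUE),
                          stats::sd(a, na.rm = TRUE)),
      missing = sprintf("%.2f (%.2f)", mean(m, na.rm = TRUE),
                        stats::sd(m, na.rm = TRUE)),
      test = "t-test", p = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- factor(tab[[v]])
    cmpl <- factor(complete, levels = c(TRUE, FALSE))
    ct <- table(x, cmpl)
    res <- if (nrow(ct) < 2 || any(colSums(ct) == 0)) {
      list(test = "none", p = NA_real_)
    } else {
      expected <- outer(rowSums(ct), colSums(ct)) / sum(ct)
      if (any(expected < 5)) {
        list(test = "Fisher", p = stats::fisher.test(ct)$p.value)
      } else {
        list(test = "chi-square",
             p = suppressWarnings(stats::chisq.test(ct)$p.value))
      }
    }
    summarise <- function(flag) {
      n <- table(x[flag])
      paste(sprintf("%s:%d", names(n), as.integer(n)), collapse = " ")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = v, type = "categorical",
      available = summarise(complete), missing = summarise(!complete),
      test = res$test, p = res$p, stringsAsFactors = FALSE)
  }
  structure(list(complete = tab[complete, , drop = FALSE],
                 n_available = sum(complete), n_missing = sum(!complete),
                 report = do.call(rbind, rows)),
            class = "complete_case_result")
}

#' @export
print.complete_case_result <- function(x, ...) {
  cat("Complete cases:", x$n_available, "available,", x$n_missing,
      "missing\n")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Last value carried forward
#'
#' Single imputation: a missing utility takes the participant's most recent
#' observed utility; a missing period cost takes the most recent observed
#' same-category period cost, with the baseline period cost
#' (`baseline_cost` for healthcare, `baseline_social_cost` for social care,
#' zero if absent) standing in for weeks 0-10.
#'
#' @param tab wide analysis table; `u0` and `baseline_cost` must be
#'   observed for every participant.
#' @return an `imputation_set` with `m = 1` completed dataset.
#' @export
locf_impute <- function(tab) {
  if (anyNA(tab$u0) || anyNA(tab$baseline_cost)) {
    stop("baseline utility and baseline cost must be observed for LOCF")
  }
  out <- tab
  out$u10 <- ifelse(is.na(out$u10), out$u0, out$u10)
  out$u20 <- ifelse(is.na(out$u20), out$u10, out$u20)
  base_soc <- if ("baseline_social_cost" %in% names(out) &&
                  !anyNA(out$baseline_social_cost)) {
    out$baseline_social_cost
  } else rep(0, nrow(out))
  out$hc_cost_1 <- ifelse(is.na(out$hc_cost_1), out$baseline_cost,
                          out$hc_cost_1)
  out$hc_cost_2 <- ifelse(is.na(out$hc_cost_2), out$hc_cost_1, out$hc_cost_2)
  out$soc_cost_1 <- ifelse(is.na(out$soc_cost_1), base_soc, out$soc_cost_1)
  out$soc_cost_2 <- ifelse(is.na(out$soc_cost_2), out$soc_cost_1,
                           out$soc_cost_2)
  structure(list(datasets = list(out), m = 1L, method = "LOCF",
                 iterations = NA_integer_, seed = NA_integer_),
            class = "imputation_set")
}

bayes_lm_draw <- function(y, X, X_mis) {
  keep <- qr(X)$pivot[seq_len(qr(X)$rank)]
  X <- X[, keep, drop = FALSE]; X_mis <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  if (df < 1) stop("degenerate regression")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / stats::rchisq(1, df)
  XtXi <- chol2inv(chol(crossprod(X)))
  beta <- fit$coefficients + drop(chol(XtXi) %*% stats::rnorm(ncol(X))) *
    sqrt(sigma2)
  drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

bayes_logit_draw <- function(y, X, X_mis) {
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  beta <- fit$coefficients + drop(chol(V) %*% stats::rnorm(ncol(X)))
  stats::rbinom(nrow(X_mis), 1, stats::plogis(drop(X_mis %*% beta)))
}

#' Multiple imputation by chained equations
#'
#' Fills each incomplete analysis variable in turn by drawing from a
#' Bayesian regression on the predictors and the other (currently imputed)
#' incomplete variables: normal linear-model draws for continuous
#' variables, logistic draws for binary ones, cycling `iterations` times
#' per imputation. Observed cells are never modified. A degenerate model
#' (constant predictor, insufficient residual degrees of freedom) falls
#' back to a marginal mean/mode draw with a warning.
#'
#' @param tab wide analysis table.
#' @param m number of imputations (default 5).
#' @param iterations chained-equation cycles per imputation (default 10).
#' @param seed integer seed.
#' @param predictors complete covariate columns used in every model.
#' @param impute_vars incomplete columns to fill; defaults to the analysis
#'   variables present with any missingness.
#' @return an `imputation_set`: `datasets` (list of m completed tables),
#'   `m`, `iterations`, `seed`, `method = "MICE"`.
#' @export
mice_impute <- function(tab, m = 5, iterations = 10, seed = NULL,
                        predictors = c("arm", "male", "age", "u0",
                                       "baseline_cost"),
                        impute_vars = NULL) {
  if (!is.null(seed)) set.seed(seed)
  predictors <- intersect(predictors, names(tab))
  if (is.null(impute_vars)) {
    impute_vars <- intersect(ANALYSIS_VARS, names(tab))
  }
  impute_vars <- impute_vars[vapply(impute_vars,
                                    function(v) anyNA(tab[[v]]), logical(1))]
  pred_frame <- tab[predictors]
  # arm enters as an indicator; factors expand via model.matrix
  base_X <- stats::model.matrix(~ ., data = data.frame(
    lapply(pred_frame, function(x) if (is.character(x)) factor(x) else x)))
  if (anyNA(base_X)) stop("predictors must be fully observed")
  is_binary <- vapply(impute_vars, function(v) {
    all(tab[[v]] %in% c(0, 1, NA))
  }, logical(1))
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    cur <- tab
    # initialise missing cells from the observed marginal distribution
    for (v in impute_vars) {
      mis <- is.na(cur[[v]])
      obs <- cur[[v]][!mis]
      if (!length(obs)) stop("variable '", v, "' has no observed values")
      cur[[v]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in impute_vars) {
        mis <- is.na(tab[[v]])
        if (!any(mis)) next
        others <- setdiff(impute_vars, v)
        X_all <- cbind(base_X,
                       if (length(others))
                         as.matrix(cur[others]) else NULL)
        y_obs <- tab[[v]][!mis]
        draw <- tryCatch({
          if (is_binary[[v]]) {
            bayes_logit_draw(y_obs, X_all[!mis, , drop = FALSE],
                             X_all[mis, , drop = FALSE])
          } else {
            bayes_lm_draw(y_obs, X_all[!mis, , drop = FALSE],
                          X_all[mis, , drop = FALSE])
          }
        }, error = function(e) {
          warning("degenerate model for '", v,
                  "'; falling back to a marginal draw", call. = FALSE)
          if (is_binary[[v]]) {
            stats::rbinom(sum(mis), 1, mean(y_obs))
          } else {
            stats::rnorm(sum(mis), mean(y_obs), stats::sd(y_obs))
          }
        })
        cur[[v]][mis] <- draw
      }
    }
    datasets[[k]] <- cur
  }
  structure(list(datasets = datasets, m = as.integer(m),
                 iterations = as.integer(iterations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 method = "MICE"),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(x$method, "imputation:", x$m, "completed dataset(s)",
      if (!is.na(x$iterations)) paste0("(", x$iterations, " iterations)"),
      "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance is the within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance, with Rubin's degrees of freedom for the
#' interval.
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors.
#' @param conf_level confidence level.
#' @return list: `estimate`, `variance`, `within`, `between`, `df`, `ci`.
#' @export
pool_estimates <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) {
    stop("pooling needs m >= 2 imputations; analyse a single dataset directly")
  }
  if (length(variances) != m || any(!is.finite(variances))) {
    stop("variances must be finite and match the estimates")
  }
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between > 0) {
    (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
  } else Inf
  half <- stats::qt(1 - (1 - conf_level) / 2, df) * sqrt(total)
  list(estimate = qbar, variance = total, within = within, between = between,
       df = df, ci = c(qbar - half, qbar + half))
}

#' Cost-effectiveness analysis under multiple imputation
#'
#' Runs the bootstrap cost-effectiveness analysis on each completed dataset
#' and combines: acceptability curves are averaged pointwise across
#' imputations; the ICER is computed from the pooled (mean) cost and QALY
#' differences.
#'
#' @param imputations an `imputation_set`.
#' @param ce_input_fn function mapping one completed analysis table to a
#'   data.frame with `arm`, `cost`, `qaly` (see [ce_input()]).
#' @param B bootstrap replications per imputation.
#' @param seed integer seed; imputation k uses `seed + k`.
#' @param lambda_grid,threshold,intervention as in [run_cea()].
#' @return list: `ceac` (pointwise-average curve), `icer` (from pooled
#'   differences), `delta_cost`, `delta_qaly` (pooled means),
#'   `per_imputation` (list of `cea_result`s).
#' @export
cea_imputed <- function(imputations, ce_input_fn, B = 1000, seed = 1,
                        lambda_grid = seq(0, 100000, by = 500),
                        threshold = 20000, intervention = "intervention") {
  stopifnot(inherits(imputations, "imputation_set"))
  results <- lapply(seq_along(imputations$datasets), function(k) {
    run_cea(ce_input_fn(imputations$datasets[[k]]),
            intervention = intervention, B = B, seed = seed + k,
            lambda_grid = lambda_grid, threshold = threshold)
  })
  p_mat <- vapply(results, function(r) r$ceac$p_intervention,
                  numeric(length(lambda_grid)))
  curve <- data.frame(lambda = lambda_grid,
                      p_intervention = rowMeans(p_mat))
  curve$p_control <- 1 - curve$p_intervention
  class(curve) <- c("ceac_curve", "data.frame")
  dc <- mean(vapply(results, function(r) r$replicates$delta_cost, numeric(1)))
  dq <- mean(vapply(results, function(r) r$replicates$delta_qaly, numeric(1)))
  list(ceac = curve, icer = icer(dc, dq), delta_cost = dc, delta_qaly = dq,
       per_imputation = results)
}
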