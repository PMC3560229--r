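# Between-arm contrasts: mean differences with Welch t-tests, baseline-
# adjusted least squares, closed-form Poisson rate ratios and relative
# risks with Wald log-scale intervals, and the bias-corrected percentile
# bootstrap used for cost and QALY differences.

arm_contrast <- function(estimate, ci_low, ci_high, p = NA_real_,
                         method = "", summary = NULL, calculable = TRUE,
                         degenerate = FALSE) {
  structure(list(estimate = estimate, ci = c(ci_low, ci_high), p = p,
                 method = method, summary = summary,
                 calculable = calculable, degenerate = degenerate),
            class = "arm_contrast")
}

#' @export
print.arm_contrast <- function(x, digits = 3, ...) {
  if (!x$calculable) {
    cat("Not calculable (", x$method, ")\n", sep = "")
    return(invisible(x))
  }
  cat(format(round(x$estimate, digits)), " (95% CI ",
      format(round(x$ci[1], digits)), " to ",
      format(round(x$ci[2], digits)), ")",
      if (!is.na(x$p)) paste0(", p = ", format.pval(x$p, digits = 3)),
      "  [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Difference in arm means with a t-test
#'
#' Mean of arm A minus mean of arm B, with a two-sided t-test. Costs are
#' typically skewed, but inference targets the arithmetic mean, so the
#' t-test on raw values is used; the unequal-variance (Welch) form is the
#' default.
#'
#' @param x,y values in arm A and arm B (each of length >= 2).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param conf_level confidence level.
#' @return an `arm_contrast`.
#' @export
mean_difference <- function(x, y, var_equal = FALSE, conf_level = 0.95) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each arm needs at least two observations for a t-test")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal, conf.level = conf_level)
  arm_contrast(mean(x) - mean(y), tt$conf.int[1], tt$conf.int[2],
               p = tt$p.value,
               method = if (var_equal) "t-test (pooled)" else "t-test (Welch)",
               summary = list(
                 a = c(n = length(x), mean = mean(x), sd = stats::sd(x)),
                 b = c(n = length(y), mean = mean(y), sd = stats::sd(y))))
}

#' Bias-corrected percentile bootstrap confidence interval
#'
#' Stratified non-parametric bootstrap for a two-arm statistic: each
#' replicate resamples participants with replacement within arm, preserving
#' the arm sizes, and re-evaluates `statistic`. The bias-correction
#' constant is `z0 = qnorm(P(theta* < theta_hat))`; interval endpoints are
#' the bootstrap quantiles at `pnorm(2*z0 -/+ z_(alpha/2))` (the BC, not
#' BCa, interval: no acceleration term).
#'
#' @param x,y observations (or rows) for arm A and arm B. Vectors, or
#'   data.frames resampled by row.
#' @param statistic `function(x, y)` returning a scalar; default mean
#'   difference A - B.
#' @param B bootstrap replications (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param conf_level confidence level.
#' @return an `arm_contrast`; `degenerate = TRUE` (and a collapsed interval)
#'   when every replicate equals the point estimate. The replicate draws
#'   are attached as attribute `"replicates"`.
#' @export
bootstrap_bc_ci <- function(x, y, statistic = function(x, y) mean(x) - mean(y),
                            B = 1000, seed = NULL, conf_level = 0.95) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  take <- function(v, idx) if (is.data.frame(v)) v[idx, , drop = FALSE] else v[idx]
  n_of <- function(v) if (is.data.frame(v)) nrow(v) else length(v)
  nx <- n_of(x); ny <- n_of(y)
  if (nx < 1 || ny < 1) stop("both arms must be nonempty")
  theta_hat <- statistic(x, y)
  theta_star <- vapply(seq_len(B), function(b) {
    statistic(take(x, sample.int(nx, nx, replace = TRUE)),
              take(y, sample.int(ny, ny, replace = TRUE)))
  }, numeric(1))
  out <- bc_interval(theta_hat, theta_star, conf_level)
  attr(out, "replicates") <- theta_star
  out
}

# BC interval from a point estimate and replicate draws (shared with the
# joint cost-effectiveness bootstrap).
bc_interval <- function(theta_hat, theta_star, conf_level = 0.95) {
  B <- length(theta_star)
  if (all(theta_star == theta_star[1]) && theta_star[1] == theta_hat) {
    return(arm_contrast(theta_hat, theta_hat, theta_hat,
                        method = "bootstrap BC", degenerate = TRUE))
  }
  prop_below <- mean(theta_star < theta_hat)
  # guard the normal quantile at the replicate resolution
  prop_below <- min(max(prop_below, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop_below)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(theta_star, probs, type = 7))
  arm_contrast(theta_hat, ci[1], ci[2], method = "bootstrap BC")
}

#' Poisson rate ratio for contact counts
#'
#' Closed-form two-group Poisson contrast: rate ratio
#' `(events_a/n_a) / (events_b/n_b)` with a Wald interval on the log scale
#' (variance `1/events_a + 1/events_b`), equivalent to Poisson regression
#' of counts on arm with log person-exposure offset. When either arm has
#' zero events the ratio is reported as not calculable, mirroring how
#' trial resource-use tables print such cells.
#'
#' @param events_a,events_b total event counts per arm.
#' @param n_a,n_b exposure (participants over the common window) per arm.
#' @param conf_level confidence level.
#' @return an `arm_contrast` (`calculable = FALSE` when a zero count blocks
#'   the log-scale interval).
#' @examples
#' poisson_rate_ratio(3, 48, 15, 45)  # 0.19 (0.05 to 0.65)
#' @export
poisson_rate_ratio <- function(events_a, n_a, events_b, n_b,
                               conf_level = 0.95) {
  if (n_a <= 0 || n_b <= 0) stop("exposures must be positive")
  if (events_a < 0 || events_b < 0) stop("event counts must be nonnegative")
  if (events_a == 0 || events_b == 0) {
    return(arm_contrast(NA_real_, NA_real_, NA_real_,
                        method = "Poisson rate ratio", calculable = FALSE,
                        summary = list(a = c(events = events_a, n = n_a),
                                       b = c(events = events_b, n = n_b))))
  }
  rr <- (events_a / n_a) / (events_b / n_b)
  se <- sqrt(1 / events_a + 1 / events_b)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(rr) / se
  arm_contrast(rr, exp(log(rr) - zc * se), exp(log(rr) + zc * se),
               p = 2 * stats::pnorm(-abs(z)), method = "Poisson rate ratio",
               summary = list(a = c(events = events_a, n = n_a),
                              b = c(events = events_b, n = n_b)))
}

#' Relative risk of any use of a service
#'
#' Risk ratio `(a/n_a) / (b/n_b)` with the Katz log-method Wald interval
#' (variance `1/a - 1/n_a + 1/b - 1/n_b`). A zero numerator in either arm
#' yields a not-calculable result.
#'
#' @param a,b numbers of users per arm.
#' @param n_a,n_b numbers at risk per arm.
#' @param conf_level confidence level.
#' @return an `arm_contrast`.
#' @examples
#' relative_risk(2, 48, 1, 45)  # 1.88 (0.18 to 19.97)
#' @export
relative_risk <- function(a, n_a, b, n_b, conf_level = 0.95) {
  if (n_a <= 0 || n_b <= 0) stop("denominators must be positive")
  if (a < 0 || b < 0 || a > n_a || b > n_b) stop("invalid 2x2 counts")
  if (a == 0 || b == 0) {
    return(arm_contrast(NA_real_, NA_real_, NA_real_,
                        method = "relative risk (Katz)", calculable = FALSE,
                        summary = list(a = c(users = a, n = n_a),
                                       b = c(users = b, n = n_b))))
  }
  rr <- (a / n_a) / (b / n_b)
  se <- sqrt(1 / a - 1 / n_a + 1 / b - 1 / n_b)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(rr) / se
  arm_contrast(rr, exp(log(rr) - zc * se), exp(log(rr) + zc * se),
               p = 2 * stats::pnorm(-abs(z)), method = "relative risk (Katz)",
               summary = list(a = c(users = a, n = n_a),
                              b = c(users = b, n = n_b)))
}

#' Baseline-adjusted arm difference by least squares
#'
#' Ordinary least squares of the outcome on an arm indicator and a baseline
#' covariate; the arm coefficient is the adjusted between-arm difference,
#' with its Wald interval.
#'
#' @param outcome numeric outcome (e.g. follow-up cost).
#' @param arm indicator: 1/TRUE for the arm whose effect is reported.
#' @param baseline numeric baseline covariate (e.g. pre-trial cost).
#' @param conf_level confidence level.
#' @return an `arm_contrast`.
#' @export
ols_adjusted_difference <- function(outcome, arm, baseline,
                                    conf_level = 0.95) {
  arm <- as.numeric(arm)
  ok <- stats::complete.cases(outcome, arm, baseline)
  if (!all(ok)) stop("adjusted comparison requires complete rows")
  if (stats::sd(arm) == 0) stop("arm indicator is constant")
  # a constant baseline carries no information and drops out of the model,
  # leaving the unadjusted comparison; a baseline collinear with arm makes
  # the arm effect unidentifiable and is an error
  fit <- if (stats::sd(baseline) == 0) stats::lm(outcome ~ arm)
         else stats::lm(outcome ~ arm + baseline)
  if (anyNA(stats::coef(fit))) {
    stop("baseline covariate collinear with arm; adjustment unidentifiable")
  }
  est <- stats::coef(fit)[["arm"]]
  ci <- stats::confint(fit, "arm", level = conf_level)
  p <- summary(fit)$coefficients["arm", "Pr(>|t|)"]
  arm_contrast(est, ci[1], ci[2], p = p, method = "OLS baseline-adjusted")
}
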