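# QALYs from EQ-5D utility trajectories: trapezoidal area under the curve
# with linear interpolation between assessments, and a death rule that
# registers zero utility from the assessment period in which death occurred.

#' EQ-5D index bounds (UK value set)
#'
#' Published index values range from 1.00 (best health) to -0.594 (worst
#' health); 0 is equivalent to death.
#' @export
EQ5D_BOUNDS <- c(-0.594, 1.00)

#' Trapezoid weights for the QALY area under the curve
#'
#' QALYs computed by [qaly_auc()] are an exact linear functional of the
#' utilities: the dot product with these weights. Exposed for oracle
#' checking and for closed-form variance work.
#'
#' @param weeks strictly increasing assessment weeks, first at 0.
#' @param weeks_per_year weeks in a year (default 52).
#' @return numeric weight vector, same length as `weeks`.
#' @export
qaly_weights <- function(weeks, weeks_per_year = 52) {
  stopifnot(length(weeks) >= 2, all(diff(weeks) > 0))
  n <- length(weeks)
  w <- numeric(n)
  w[1] <- (weeks[2] - weeks[1]) / 2
  if (n > 2) w[2:(n - 1)] <- (weeks[3:n] - weeks[1:(n - 2)]) / 2
  w[n] <- (weeks[n] - weeks[n - 1]) / 2
  w / weeks_per_year
}

apply_death_rule <- function(weeks, utilities, death_week,
                             death_rule = c("assessment", "exact")) {
  death_rule <- match.arg(death_rule)
  if (is.null(death_week) || is.na(death_week)) {
    return(list(weeks = weeks, utilities = utilities))
  }
  if (death_week <= 0) stop("death_week must be positive")
  if (death_rule == "assessment") {
    # zero from the first scheduled assessment at or after death; linear
    # interpolation runs from the last pre-death assessment down to zero
    utilities[weeks >= death_week] <- 0
    list(weeks = weeks, utilities = utilities)
  } else {
    # zero from the exact death date: insert (death_week, 0)
    keep <- weeks < death_week
    w <- c(weeks[keep], death_week, weeks[!keep])
    u <- c(utilities[keep], 0, rep(0, sum(!keep)))
    dup <- duplicated(w)
    list(weeks = w[!dup], utilities = u[!dup])
  }
}

#' QALYs over a trial horizon by area under the utility curve
#'
#' Integrates the piecewise-linear utility curve over `[0, horizon_weeks]`
#' and converts to years. Participants who died have utility registered as
#' zero from the assessment period in which the death occurred
#' (`death_rule = "assessment"`, the default) or from the exact death date
#' (`death_rule = "exact"`).
#'
#' @param weeks strictly increasing assessment weeks, first at 0, covering
#'   the horizon.
#' @param utilities EQ-5D index values at `weeks`; `NA` only where resolved
#'   by the death rule.
#' @param death_week optional week of death in `(0, horizon]`.
#' @param horizon_weeks analysis horizon (default 20).
#' @param weeks_per_year annualisation constant (default 52).
#' @param death_rule see above.
#' @return list with `qalys` (years) and `complete` (logical: all needed
#'   utilities observed or resolved by the death rule).
#' @examples
#' qaly_auc(c(0, 10, 20), c(0.70, 0.66, 0.74))  # ~0.2654
#' @export
qaly_auc <- function(weeks, utilities, death_week = NA_real_,
                     horizon_weeks = 20, weeks_per_year = 52,
                     death_rule = c("assessment", "exact")) {
  death_rule <- match.arg(death_rule)
  stopifnot(length(weeks) == length(utilities), length(weeks) >= 2)
  if (any(diff(weeks) <= 0)) stop("assessment weeks must be strictly increasing")
  if (weeks[1] != 0) stop("first assessment must be at week 0 (baseline)")
  if (horizon_weeks > max(weeks)) {
    stop("horizon (", horizon_weeks, " weeks) extends beyond the last ",
         "assessment (week ", max(weeks), ")")
  }
  resolved <- apply_death_rule(weeks, utilities, death_week, death_rule)
  w <- resolved$weeks
  u <- resolved$utilities
  in_horizon <- w <= horizon_weeks
  if (anyNA(u[in_horizon])) {
    stop("missing utility at week(s) ",
         paste(w[in_horizon][is.na(u[in_horizon])], collapse = ", "),
         " not resolved by the death rule; impute before computing QALYs")
  }
  ok <- !is.na(u) & (u >= EQ5D_BOUNDS[1] - 1e-9) & (u <= EQ5D_BOUNDS[2] + 1e-9)
  if (!all(ok[in_horizon])) {
    stop("utilities outside the EQ-5D index range [",
         EQ5D_BOUNDS[1], ", ", EQ5D_BOUNDS[2], "]")
  }
  w <- w[in_horizon]
  u <- u[in_horizon]
  if (max(w) < horizon_weeks) {
    # horizon falls inside the last interval (exact death rule inserts nodes)
    stop("assessments do not span the horizon after death resolution")
  }
  auc <- sum((u[-1] + u[-length(u)]) / 2 * diff(w)) / weeks_per_year
  list(qalys = auc, complete = TRUE)
}

#' QALYs for every participant in a wide analysis table
#'
#' @param tab analysis table with utility columns `u0`, `u10`, `u20` (or as
#'   named via `utility_cols`) and optional `death_week`.
#' @param weeks assessment weeks matching the utility columns.
#' @param utility_cols names of the utility columns in `tab`.
#' @param ... passed to [qaly_auc()].
#' @return numeric vector of QALYs (NA where the trajectory is incomplete
#'   and not resolved by the death rule).
#' @export
qalys_from_table <- function(tab, weeks = c(0, 10, 20),
                             utility_cols = c("u0", "u10", "u20"), ...) {
  stopifnot(all(utility_cols %in% names(tab)))
  dw <- if ("death_week" %in% names(tab)) tab$death_week else
    rep(NA_real_, nrow(tab))
  vapply(seq_len(nrow(tab)), function(i) {
    u <- as.numeric(tab[i, utility_cols])
    res <- tryCatch(qaly_auc(weeks, u, death_week = dw[i], ...),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$qalys
  }, numeric(1))
}
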