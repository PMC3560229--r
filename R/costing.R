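# Applying the tariff to resource-use records, and micro-costing the
# delivery of the group exercise intervention.

RESOURCE_CATEGORIES <- c("medication", "acute", "primary", "social")

validate_resource_records <- function(records, tariff) {
  needed <- c("id", "category", "item", "amount", "period")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("resource records lack columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) return(invisible(records))
  if (any(is.na(records$amount)) || any(records$amount < 0)) {
    stop("resource amounts must be nonnegative and non-missing")
  }
  bad <- !(records$category %in% RESOURCE_CATEGORIES)
  if (any(bad)) {
    stop("unknown resource categories: ",
         paste(unique(records$category[bad]), collapse = ", "))
  }
  key <- paste(records$category, records$item, sep = "/")
  tariff_key <- paste(tariff$entries$category, tariff$entries$item, sep = "/")
  unresolved <- setdiff(unique(key), tariff_key)
  if (length(unresolved)) {
    stop("resource items missing from tariff: ",
         paste(unresolved, collapse = ", "))
  }
  invisible(records)
}

record_cost_pence <- function(records, tariff) {
  if (nrow(records) == 0L) return(integer(0))
  tariff_key <- paste(tariff$entries$category, tariff$entries$item, sep = "/")
  price <- tariff$entries$price[match(paste(records$category, records$item,
                                            sep = "/"), tariff_key)]
  # each record is rounded to the penny; sums are then exact by construction
  as.integer(round(records$amount * price * 100))
}

#' Cost resource-use records against a tariff
#'
#' Each record's cost is its amount times the tariff unit price, rounded to
#' the penny; per-category and total sums are conserved to the penny.
#' Participants listed in `ids` but absent from `records` receive an
#' all-zero breakdown, keeping them in analysis denominators.
#'
#' @param records data.frame with columns `id`, `category` (one of
#'   medication/acute/primary/social), `item`, `amount`, `period`.
#' @param tariff a [unit_cost_tariff()].
#' @param ids optional vector of participant ids defining the denominator;
#'   defaults to the ids present in `records`.
#' @return data.frame of class `cost_breakdown`: one row per id with pounds
#'   per category, `total_healthcare` (medication + acute + primary) and
#'   `total_combined` (healthcare + social).
#' @export
cost_resource_use <- function(records, tariff, ids = NULL) {
  stopifnot(inherits(tariff, "unit_cost_tariff"))
  validate_resource_records(records, tariff)
  if (is.null(ids)) ids <- unique(records$id)
  pence <- record_cost_pence(records, tariff)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (cat in RESOURCE_CATEGORIES) {
    sel <- records$category == cat
    tot <- tapply(pence[sel], factor(records$id[sel], levels = ids), sum)
    tot[is.na(tot)] <- 0L
    out[[cat]] <- pence_to_pounds(as.integer(tot))
  }
  out$total_healthcare <- out$medication + out$acute + out$primary
  out$total_combined <- out$total_healthcare + out$social
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Per-period, per-category costs
#'
#' Long-format companion of [cost_resource_use()]: pounds per participant,
#' assessment period and category, for period-level analyses such as
#' last-value-carried-forward imputation.
#'
#' @inheritParams cost_resource_use
#' @return data.frame with columns `id`, `period`, one column per category
#'   (pounds), `healthcare` and `combined` totals.
#' @export
period_costs <- function(records, tariff, ids = NULL) {
  stopifnot(inherits(tariff, "unit_cost_tariff"))
  validate_resource_records(records, tariff)
  if (is.null(ids)) ids <- unique(records$id)
  periods <- unique(records$period)
  pence <- record_cost_pence(records, tariff)
  grid <- expand.grid(id = ids, period = periods, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  for (cat in RESOURCE_CATEGORIES) {
    sel <- records$category == cat
    idx <- interaction(factor(records$id[sel], levels = ids),
                       factor(records$period[sel], levels = periods),
                       drop = FALSE)
    tot <- tapply(pence[sel], idx, sum)
    tot[is.na(tot)] <- 0L
    grid[[cat]] <- pence_to_pounds(as.integer(tot))
  }
  grid$healthcare <- grid$medication + grid$acute + grid$primary
  grid$combined <- grid$healthcare + grid$social
  grid
}

#' Micro-cost the group exercise intervention
#'
#' Sums the delivery components (venue hire, therapist time, therapist
#' travel, equipment) and reports the mean cost per randomised participant,
#' assuming all randomised participants attend. The alternative-group-size
#' scenario rescales the components that vary with the number of groups run
#' (venue, therapist time and travel) by the ratio of group counts
#' `ceiling(n/new_size) / ceiling(n/old_size)`, holding equipment fixed —
#' an explicit modelling assumption, since courses are booked per group.
#'
#' @param venue,staff_time,staff_travel,equipment delivery components in
#'   pounds (per full course of groups).
#' @param n_randomised participants randomised to the intervention arm.
#' @param achieved_group_size mean achieved participants per group.
#' @param scenario_group_size group size for the scenario re-costing
#'   (default 6, the protocol maximum); `NULL` skips the scenario.
#' @return list with `total` (pounds), `per_participant` (nearest pound),
#'   `components`, and if requested `scenario` (total, per_participant).
#' @examples
#' cost_intervention(448, 3900, 335, 200, n_randomised = 64)
#' @export
cost_intervention <- function(venue, staff_time, staff_travel, equipment,
                              n_randomised, achieved_group_size = 4,
                              scenario_group_size = 6) {
  comp <- c(venue = venue, staff_time = staff_time,
            staff_travel = staff_travel, equipment = equipment)
  if (any(!is.finite(comp)) || any(comp < 0)) {
    stop("intervention cost components must be nonnegative")
  }
  if (!is.finite(n_randomised) || n_randomised <= 0) {
    stop("n_randomised must be positive")
  }
  total <- sum(comp)
  out <- list(total = total,
              per_participant = round(total / n_randomised),
              components = comp)
  if (!is.null(scenario_group_size)) {
    old_groups <- ceiling(n_randomised / achieved_group_size)
    new_groups <- ceiling(n_randomised / scenario_group_size)
    scale <- new_groups / old_groups
    sc_total <- (venue + staff_time + staff_travel) * scale + equipment
    out$scenario <- list(group_size = scenario_group_size,
                         n_groups = new_groups,
                         total = round_penny(sc_total),
                         per_participant = round(sc_total / n_randomised))
  }
  class(out) <- "intervention_cost"
  out
}

#' @export
print.intervention_cost <- function(x, ...) {
  cat("Intervention delivery cost: GBP", format(x$total, big.mark = ","),
      "\n  components:", paste(names(x$components), x$components,
                               sep = "=", collapse = ", "),
      "\n  per randomised participant: GBP", x$per_participant, "\n")
  if (!is.null(x$scenario)) {
    cat("  scenario at group size", x$scenario$group_size, ": GBP",
        x$scenario$total, "total, GBP", x$scenario$per_participant,
        "per participant\n")
  }
  invisible(x)
}

#' Participant travel cost for attending group sessions
#'
#' Return-journey mileage cost: `2 * distance * sessions * rate`, rounded
#' to the penny.
#'
#' @param distance one-way distance in miles.
#' @param sessions number of sessions attended.
#' @param rate reimbursement rate in pounds per mile.
#' @return cost in pounds.
#' @export
participant_travel_cost <- function(distance, sessions, rate) {
  if (any(distance < 0) || any(sessions < 0) || any(rate < 0)) {
    stop("travel inputs must be nonnegative")
  }
  round_penny(2 * distance * sessions * rate)
}
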