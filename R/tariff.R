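# Unit-cost tariff: each entry carries the price actually charged per unit
# plus the derivation basis it was computed from, so the tariff can be
# audited (re-deriving every price from its basis must reproduce it exactly).

#' Derive a unit cost from its stated basis
#'
#' Supported rules: `identity` (price quoted directly), `multiply` (product
#' of components, e.g. an inflator applied to a reference price, or an hourly
#' rate times a contact length), `divide` (first component divided by the
#' second, e.g. a weekly care-package price to a per-day price), and
#' `per_hour` (hourly rate times minutes/60).
#'
#' @param rule one of `"identity"`, `"multiply"`, `"divide"`, `"per_hour"`.
#' @param components numeric vector of positive components, interpreted per
#'   rule; for `per_hour` the components are `c(rate_per_hour, minutes)`.
#' @param rounding penny rounding convention, see [round_penny()].
#' @param entry optional entry label used in error messages.
#' @return price in pounds, exact to the penny.
#' @examples
#' derive_unit_cost("multiply", c(205, 1.04))        # 213.20
#' derive_unit_cost("divide", c(958, 7))             # 136.86
#' derive_unit_cost("divide", c(35, 3), "truncate")  # 11.66
#' @export
derive_unit_cost <- function(rule, components,
                             rounding = c("half_up", "truncate"),
                             entry = NULL) {
  rounding <- match.arg(rounding)
  if (!is.numeric(components) || any(!is.finite(components)) ||
      any(components < 0)) {
    stop("components must be finite and nonnegative",
         if (!is.null(entry)) paste0(" for entry '", entry, "'"))
  }
  raw <- switch(rule,
    identity = components[[1L]],
    multiply = prod(components),
    divide   = {
      if (length(components) != 2L || components[[2L]] == 0) {
        stop("divide rule needs two components with a nonzero divisor",
             if (!is.null(entry)) paste0(" for entry '", entry, "'"))
      }
      components[[1L]] / components[[2L]]
    },
    per_hour = {
      if (length(components) != 2L) {
        stop("per_hour rule needs c(rate_per_hour, minutes)",
             if (!is.null(entry)) paste0(" for entry '", entry, "'"))
      }
      components[[1L]] * components[[2L]] / 60
    },
    stop("unknown derivation rule '", rule, "'",
         if (!is.null(entry)) paste0(" for entry '", entry, "'"))
  )
  round_penny(raw, rounding)
}

#' Construct a unit-cost tariff
#'
#' @param entries a data.frame with columns `category`, `item`, `unit`,
#'   `price` (pounds), `rule`, `components` (list column of numeric
#'   vectors), `rounding`; one row per costed item.
#' @param price_year label for the financial year of the prices.
#' @return an object of class `unit_cost_tariff`.
#' @export
unit_cost_tariff <- function(entries, price_year = "2008/9") {
  needed <- c("category", "item", "unit", "price", "rule", "components",
              "rounding")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols)) {
    stop("tariff entries lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(entries$price < 0)) stop("tariff prices must be nonnegative")
  key <- paste(entries$category, entries$item, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate tariff entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  # audit: every stored price must re-derive exactly from its basis
  for (i in seq_len(nrow(entries))) {
    rederived <- derive_unit_cost(entries$rule[[i]], entries$components[[i]],
                                  entries$rounding[[i]], entry = key[[i]])
    if (!identical(pounds_to_pence(rederived),
                   pounds_to_pence(entries$price[[i]]))) {
      stop("stored price ", entries$price[[i]], " for '", key[[i]],
           "' does not re-derive from its basis (got ", rederived, ")")
    }
  }
  structure(list(entries = entries, price_year = price_year),
            class = "unit_cost_tariff")
}

tariff_entry <- function(category, item, unit, rule, components,
                         rounding = "half_up") {
  data.frame(category = category, item = item, unit = unit,
             price = derive_unit_cost(rule, components, rounding),
             rule = rule,
             components = I(list(components)),
             rounding = rounding,
             stringsAsFactors = FALSE)
}

#' Default health and social care unit-cost tariff
#'
#' UK 2008/9 unit costs for the primary-care, hospital and social-care items
#' costed in the analysis, each with its derivation basis: e.g. an acute
#' bed day is a reference inpatient rehabilitation price of 205 GBP inflated
#' by 1.04; a day of residential care is a 958 GBP short-term resident week
#' divided by 7; an hour of day care is a 35 GBP three-hour session divided
#' by 3 (truncated, as printed tariffs drop the recurring fraction).
#' Medication enters as a pre-priced item (amount recorded in pounds, unit
#' price 1), since drug costs are valued upstream per prescription.
#' Hospitalisation and binary medication-class items carry a zero price:
#' they are contact/usage indicators analysed as counts, costed through
#' their component items (bed days; priced medication).
#'
#' @return a [unit_cost_tariff()].
#' @export
default_tariff <- function() {
  entries <- rbind(
    tariff_entry("primary", "gp_surgery",        "visit", "identity", 36),
    tariff_entry("primary", "gp_home_visit",     "visit", "identity", 58),
    tariff_entry("primary", "practice_nurse",    "visit", "identity", 11),
    tariff_entry("primary", "community_nurse",   "visit", "identity", 26),
    tariff_entry("acute", "inpatient_bed_day",   "bed-day", "multiply",
                 c(205, 1.04)),
    tariff_entry("acute", "day_admission",       "attendance", "identity", 138),
    tariff_entry("acute", "ae_attendance",       "attendance", "identity", 111),
    tariff_entry("acute", "miu_attendance",      "attendance", "identity", 35),
    tariff_entry("acute", "outpatient_first",    "appointment", "identity", 55),
    tariff_entry("acute", "outpatient_followup", "appointment", "identity", 71),
    tariff_entry("acute", "pdns_appointment",    "appointment", "identity", 15),
    tariff_entry("acute", "pdns_home_visit",     "visit", "per_hour",
                 c(40, 25), rounding = "truncate"),
    tariff_entry("acute", "hospitalisation",     "admission", "identity", 0),
    tariff_entry("social", "care_assessment",    "assessment", "multiply",
                 c(138, 3)),
    tariff_entry("social", "home_care_hour",     "hour", "identity", 19.30),
    tariff_entry("social", "day_care_hour",      "hour", "divide",
                 c(35, 3), rounding = "truncate"),
    tariff_entry("social", "residential_care_day", "day", "divide", c(958, 7)),
    tariff_entry("social", "nursing_care_day",   "day", "divide", c(656, 7)),
    tariff_entry("medication", "parkinsons_medication", "pound", "identity", 1),
    tariff_entry("medication", "lct",  "indicator", "identity", 0),
    tariff_entry("medication", "ga",   "indicator", "identity", 0),
    tariff_entry("medication", "ac",   "indicator", "identity", 0),
    tariff_entry("medication", "cti",  "indicator", "identity", 0),
    tariff_entry("medication", "dra",  "indicator", "identity", 0),
    tariff_entry("medication", "mobi", "indicator", "identity", 0)
  )
  unit_cost_tariff(entries, price_year = "2008/9")
}

#' Look up a unit price
#'
#' @param tariff a [unit_cost_tariff()].
#' @param category,item entry key.
#' @return price in pounds.
#' @export
tariff_price <- function(tariff, category, item) {
  stopifnot(inherits(tariff, "unit_cost_tariff"))
  hit <- tariff$entries$category == category & tariff$entries$item == item
  if (sum(hit) != 1L) {
    stop("no tariff entry for (", category, ", ", item, ")")
  }
  tariff$entries$price[hit]
}

#' Write a tariff to YAML
#'
#' @param tariff a [unit_cost_tariff()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "unit_cost_tariff"))
  e <- tariff$entries
  out <- list(
    price_year = tariff$price_year,
    entries = lapply(seq_len(nrow(e)), function(i) {
      list(category = e$category[[i]], item = e$item[[i]], unit = e$unit[[i]],
           price = e$price[[i]],
           basis = list(rule = e$rule[[i]],
                        components = as.numeric(e$components[[i]])),
           rounding = e$rounding[[i]])
    })
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Read a tariff from YAML
#'
#' @param path file path written by [write_tariff()].
#' @return a [unit_cost_tariff()].
#' @export
read_tariff <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(raw$entries, function(x) {
    data.frame(category = x$category, item = x$item, unit = x$unit,
               price = as.numeric(x$price), rule = x$basis$rule,
               components = I(list(as.numeric(x$basis$components))),
               rounding = x$rounding, stringsAsFactors = FALSE)
  }))
  unit_cost_tariff(entries, price_year = raw$price_year)
}

#' @export
print.unit_cost_tariff <- function(x, ...) {
  cat("Unit-cost tariff (", x$price_year, "): ", nrow(x$entries),
      " entries\n", sep = "")
  print(x$entries[, c("category", "item", "unit", "price")], row.names = FALSE)
  invisible(x)
}
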