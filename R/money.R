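# Currency is held internally in integer pence; pounds are for display and
# interchange. This keeps category/total conservation exact.

#' Convert pounds to integer pence
#'
#' @param pounds numeric vector of amounts in pounds.
#' @return integer vector of pence.
#' @keywords internal
pounds_to_pence <- function(pounds) {
  as.integer(round(pounds * 100))
}

#' Convert integer pence to pounds
#'
#' @param pence integer vector of pence.
#' @return numeric vector of pounds.
#' @keywords internal
pence_to_pounds <- function(pence) {
  pence / 100
}

#' Round a monetary amount to the penny
#'
#' Two conventions appear in published unit-cost tariffs: commercial
#' round-half-up (the default) and truncation towards zero (used where a
#' printed tariff demonstrably drops the recurring fraction, e.g. 35/3
#' printed as 11.66).
#'
#' @param pounds numeric amount in pounds.
#' @param rounding one of `"half_up"` or `"truncate"`.
#' @return amount in pounds, exact to the penny.
#' @export
round_penny <- function(pounds, rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  pence <- switch(rounding,
    half_up  = floor(pounds * 100 + 0.5),
    truncate = trunc(pounds * 100)
  )
  pence / 100
}
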