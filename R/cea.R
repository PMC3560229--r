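# Joint cost-effectiveness layer: the incremental cost-effectiveness ratio
# with dominance classification, net monetary benefit, the bootstrap of the
# joint (cost difference, QALY difference) distribution, cost-effectiveness
# plane summaries and acceptability curves.

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies the incremental pair on the cost-effectiveness plane
#' (reference arm at the origin): the south-east quadrant (cheaper, more
#' effective) is *dominant*, the north-west (dearer, less effective) is
#' *dominated*; in the other two quadrants the ratio is a meaningful price
#' per QALY. A negative ratio is always reported together with its
#' quadrant, since the sign alone is ambiguous.
#'
#' @param delta_cost incremental cost (pounds), intervention minus control.
#' @param delta_qaly incremental QALYs, intervention minus control.
#' @return list of class `icer_result`: `ratio` (pounds/QALY, `NA` when the
#'   QALY difference is zero), `quadrant` (`"NE"`, `"SE"`, `"SW"`, `"NW"`),
#'   `classification` (`"dominant"`, `"dominated"`, `"ratio"`,
#'   `"no-ratio"`).
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  quadrant <- ce_quadrant(delta_cost, delta_qaly)
  classification <-
    if (delta_qaly == 0) "no-ratio"
    else if (delta_cost <= 0 && delta_qaly > 0) "dominant"
    else if (delta_cost > 0 && delta_qaly < 0) "dominated"
    else "ratio"
  structure(list(
    ratio = if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    quadrant = quadrant, classification = classification
  ), class = "icer_result")
}

ce_quadrant <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly >= 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_cost > 0, "NW", "SW"))
}

#' @export
print.icer_result <- function(x, ...) {
  cat("ICER:",
      if (is.na(x$ratio)) "undefined (zero QALY difference)"
      else paste0("GBP ", format(round(x$ratio), big.mark = ","), " per QALY"),
      "|", x$classification, "(", x$quadrant, "quadrant )\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * delta_qaly - delta_cost`: positive when the intervention is
#' cost-effective at willingness-to-pay `lambda` pounds per QALY.
#'
#' @param delta_cost,delta_qaly incremental cost (pounds) and QALYs.
#' @param lambda ceiling ratio, pounds per QALY (nonnegative; vectorised).
#' @return net monetary benefit in pounds.
#' @export
nmb <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  lambda * delta_qaly - delta_cost
}

#' Bootstrap the joint distribution of cost and QALY differences
#'
#' Stratified non-parametric bootstrap: each replicate resamples
#' participants with replacement within arm (original arm sizes preserved)
#' and records the pair (mean cost difference, mean QALY difference)
#' computed from the *same* resampled participants, preserving the
#' within-person cost-outcome correlation.
#'
#' @param data data.frame with columns `arm`, `cost`, `qaly` (complete
#'   cases, or one completed dataset from an imputation method).
#' @param intervention label of the intervention arm in `data$arm`.
#' @param B replications (default 1000).
#' @param seed optional integer seed.
#' @param perspective label stored with the replicates
#'   (`"healthcare"` or `"combined"`).
#' @return object of class `ce_replicates`: data.frame `replicates` with
#'   columns `delta_cost`, `delta_qaly`; point estimates `delta_cost`,
#'   `delta_qaly`; `B`, `seed`, `perspective`.
#' @export
bootstrap_joint <- function(data, intervention = "intervention", B = 1000,
                            seed = NULL, perspective = "healthcare") {
  stopifnot(all(c("arm", "cost", "qaly") %in% names(data)), B >= 1)
  if (anyNA(data$cost) || anyNA(data$qaly)) {
    stop("bootstrap requires complete cost and QALY data; filter or impute first")
  }
  is_int <- data$arm == intervention
  if (!any(is_int) || all(is_int)) stop("both arms must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  ci <- data$cost[is_int]; qi <- data$qaly[is_int]
  cc <- data$cost[!is_int]; qc <- data$qaly[!is_int]
  ni <- length(ci); nc <- length(cc)
  # index matrices: one column per replicate, arm sizes preserved
  ii <- matrix(sample.int(ni, ni * B, replace = TRUE), nrow = ni)
  ic <- matrix(sample.int(nc, nc * B, replace = TRUE), nrow = nc)
  dc <- colMeans(matrix(ci[ii], nrow = ni)) - colMeans(matrix(cc[ic], nrow = nc))
  dq <- colMeans(matrix(qi[ii], nrow = ni)) - colMeans(matrix(qc[ic], nrow = nc))
  structure(list(
    replicates = data.frame(delta_cost = dc, delta_qaly = dq),
    delta_cost = mean(ci) - mean(cc),
    delta_qaly = mean(qi) - mean(qc),
    B = B, seed = seed, perspective = perspective,
    n = c(intervention = ni, control = nc)
  ), class = "ce_replicates")
}

#' Cost-effectiveness acceptability curve
#'
#' At each ceiling ratio `lambda`, the probability that the intervention is
#' the optimal choice is estimated as the fraction of bootstrap replicates
#' with strictly positive net monetary benefit; the control's probability
#' is the complement. At `lambda = 0` this is the fraction of replicates
#' with negative cost difference; as `lambda` grows it approaches the
#' fraction with positive QALY difference.
#'
#' @param replicates a `ce_replicates` object from [bootstrap_joint()], or
#'   a data.frame with columns `delta_cost`, `delta_qaly`.
#' @param lambda_grid ceiling ratios in pounds/QALY (default 0 to 100,000
#'   by 500).
#' @return data.frame of class `ceac_curve`: `lambda`, `p_intervention`,
#'   `p_control`.
#' @export
ceac <- function(replicates, lambda_grid = seq(0, 100000, by = 500)) {
  reps <- if (inherits(replicates, "ce_replicates")) replicates$replicates
          else replicates
  stopifnot(all(c("delta_cost", "delta_qaly") %in% names(reps)),
            nrow(reps) >= 1)
  if (any(lambda_grid < 0)) stop("lambda grid must be nonnegative")
  p <- vapply(lambda_grid, function(l) {
    mean(l * reps$delta_qaly - reps$delta_cost > 0)
  }, numeric(1))
  out <- data.frame(lambda = lambda_grid, p_intervention = p,
                    p_control = 1 - p)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Write a CEAC to CSV
#'
#' Fixed column order and full-precision decimal formatting so that the
#' file is byte-stable under a fixed seed.
#'
#' @param curve a `ceac_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  df <- data.frame(lambda = curve$lambda,
                   p_intervention = format(curve$p_intervention, digits = 15,
                                           scientific = FALSE, trim = TRUE),
                   p_control = format(curve$p_control, digits = 15,
                                      scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cost-effectiveness plane summary
#'
#' Proportions of bootstrap replicates in each quadrant of the
#' cost-effectiveness plane, and the probability the intervention is
#' cost-effective at a stated willingness-to-pay threshold (identical to
#' the acceptability curve evaluated at that threshold).
#'
#' @param replicates a `ce_replicates` object or replicate data.frame.
#' @param threshold willingness-to-pay, pounds/QALY (default 20000, the
#'   lower bound of the conventional UK acceptability range).
#' @return list: `quadrants` (named proportions NE/SE/SW/NW),
#'   `threshold`, `p_cost_effective`, and the point `icer` when point
#'   estimates are available.
#' @export
ce_plane_summary <- function(replicates, threshold = 20000) {
  reps <- if (inherits(replicates, "ce_replicates")) replicates$replicates
          else replicates
  stopifnot(nrow(reps) >= 1)
  quad <- ce_quadrant(reps$delta_cost, reps$delta_qaly)
  quadrants <- vapply(c("NE", "SE", "SW", "NW"),
                      function(q) mean(quad == q), numeric(1))
  p_ce <- mean(threshold * reps$delta_qaly - reps$delta_cost > 0)
  out <- list(quadrants = quadrants, threshold = threshold,
              p_cost_effective = p_ce)
  if (inherits(replicates, "ce_replicates")) {
    out$icer <- icer(replicates$delta_cost, replicates$delta_qaly)
  }
  out
}

#' Run the full cost-effectiveness analysis on per-participant data
#'
#' Point estimates (mean differences with bias-corrected bootstrap
#' intervals), ICER with dominance classification, acceptability curve and
#' plane summary, for one cost perspective.
#'
#' @param data data.frame with `arm`, `cost`, `qaly`.
#' @param intervention intervention arm label.
#' @param B bootstrap replications.
#' @param seed integer seed.
#' @param lambda_grid ceiling-ratio grid for the acceptability curve.
#' @param threshold decision threshold, pounds/QALY.
#' @param perspective label for the cost perspective.
#' @return list of class `cea_result`: `delta_cost`, `delta_qaly`
#'   (`arm_contrast`s with BC intervals), `icer`, `ceac`, `plane`,
#'   `replicates`.
#' @export
run_cea <- function(data, intervention = "intervention", B = 1000,
                    seed = NULL, lambda_grid = seq(0, 100000, by = 500),
                    threshold = 20000, perspective = "healthcare") {
  reps <- bootstrap_joint(data, intervention = intervention, B = B,
                          seed = seed, perspective = perspective)
  dc <- bc_interval(reps$delta_cost, reps$replicates$delta_cost)
  dq <- bc_interval(reps$delta_qaly, reps$replicates$delta_qaly)
  structure(list(
    delta_cost = dc, delta_qaly = dq,
    icer = icer(reps$delta_cost, reps$delta_qaly),
    ceac = ceac(reps, lambda_grid),
    plane = ce_plane_summary(reps, threshold),
    replicates = reps, perspective = perspective
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness analysis (", x$perspective, " perspective, B = ",
      x$replicates$B, ")\n", sep = "")
  cat("  incremental cost (GBP): "); print(x$delta_cost)
  cat("  incremental QALYs:      "); print(x$delta_qaly, digits = 4)
  cat("  "); print(x$icer)
  cat("  P(cost-effective at GBP ", x$plane$threshold, "/QALY) = ",
      round(x$plane$p_cost_effective, 3), "\n", sep = "")
  invisible(x)
}
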