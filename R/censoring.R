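## Balanced interval construction for doses of heterogeneous study quality.

#' Build balanced censored intervals from per-species doses
#'
#' Literature-reported minimum effective doses are point summaries of
#' studies of very different quality: some tested tens of thousands of
#' insects over a fine dose grid, others a dozen insects at a single dose.
#' This construction represents each species' true required dose as an
#' interval. The lower bound is the highest tested dose at which treatment
#' failure was observed, floored at `min_lower_gy` (25 Gy, the lowest
#' effective dose reported in the literature); a species with no
#' sub-effective dose tested gets the floor. The upper bound stretches the
#' reported dose `D` by the species' confidence deficit:
#' \deqn{U = D + A (1 - C), \qquad A = \bar{u}_l / (1 - \bar{u}_c),}
#' where `C` is the efficacy confidence of the reported dose,
#' \eqn{\bar{u}_l} is the dataset mean of `D - lower` and \eqn{\bar{u}_c}
#' the mean confidence. The scaling `A` balances the construction: the mean
#' upper gap `mean(U - D)` equals the mean lower gap `mean(D - lower)`
#' exactly, so the intervals widen each side of the reported dose equally on
#' average while individually widening most for the least trustworthy
#' records.
#'
#' @param species_doses data frame with columns `species`, `dose_gy`,
#'   `confidence` (see [combine_dose_table()]), and optionally
#'   `highest_fail_dose_gy`. Rows with missing confidence are rejected from
#'   the censored analysis with a warning.
#' @param min_lower_gy floor for the lower bounds (default 25 Gy).
#' @return list of class `"ssd_censoring"` with `intervals` (data frame:
#'   `species`, `lower`, `reported`, `upper`, `confidence`; `lower`/`upper`
#'   are the bounds consumed by [ssd_fit()]) and `summary`
#'   (list `u_l`, `u_c`, `A`).
#' @export
build_balanced_intervals <- function(species_doses, min_lower_gy = 25) {
  if (!is.data.frame(species_doses) || nrow(species_doses) < 2L) {
    stop("at least 2 species doses are required", call. = FALSE)
  }
  d <- species_doses
  has_conf <- !is.na(d$confidence)
  if (any(!has_conf)) {
    warning(sum(!has_conf), " record(s) without a confidence value are",
      " excluded from the censored analysis", call. = FALSE)
    d <- d[has_conf, , drop = FALSE]
    if (nrow(d) < 2L) stop("too few records with confidence values", call. = FALSE)
  }
  if (any(d$confidence < 0 | d$confidence > 1)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  fail <- if ("highest_fail_dose_gy" %in% names(d)) d$highest_fail_dose_gy
    else rep(NA_real_, nrow(d))
  lower <- pmax(ifelse(is.na(fail), min_lower_gy, fail), min_lower_gy)
  lower <- pmin(lower, d$dose_gy)  # never above the reported dose

  u_l <- mean(d$dose_gy - lower)
  u_c <- mean(d$confidence)
  if (u_c >= 1) {
    stop("mean confidence is 1: the balanced construction is degenerate;",
      " fit the reported doses as exact data instead", call. = FALSE)
  }
  if (u_l == 0) {
    warning("all lower bounds equal the reported doses; intervals are",
      " degenerate", call. = FALSE)
  }
  if (all(lower == min_lower_gy) && u_l > 0) {
    warning("every lower bound sits at the common floor; the intervals are",
      " nested and the censored fit may be weakly identified (supply",
      " per-study highest failing doses for an informative censored",
      " analysis)", call. = FALSE)
  }
  A <- u_l / (1 - u_c)
  upper <- d$dose_gy + A * (1 - d$confidence)
  intervals <- data.frame(species = d$species, lower = lower,
    reported = d$dose_gy, upper = upper, confidence = d$confidence,
    stringsAsFactors = FALSE)
  structure(list(intervals = intervals,
    summary = list(u_l = u_l, u_c = u_c, A = A)),
    class = "ssd_censoring")
}

#' @export
print.ssd_censoring <- function(x, ...) {
  s <- x$summary
  cat("Balanced censored intervals for ", nrow(x$intervals), " species\n",
    "  mean lower gap u_l = ", format(s$u_l, digits = 4), " Gy, mean",
    " confidence u_c = ", format(s$u_c, digits = 4),
    ", A = ", format(s$A, digits = 4), " Gy\n", sep = "")
  invisible(x)
}
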