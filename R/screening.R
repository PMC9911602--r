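## Cook's-distance screening of extreme outlier records.

#' Flag and remove extreme-outlier dose records by Cook's distance
#'
#' Fits the ordinary least-squares screening model
#' `dose_gy ~ n_treated + highest_fail_dose_gy` to the records for which the
#' covariates are available, computes each fitted record's Cook's distance,
#' and removes records exceeding the chosen threshold. Two thresholds are
#' supported: `"four_times_mean"` (distance greater than four times the mean
#' distance, the default) and `"four_over_n"` (distance greater than 4/n).
#' A covariate that is missing for every record is dropped from the model
#' (published summary tables often omit the highest failing dose), so on
#' such tables the model reduces to `dose_gy ~ n_treated`.
#'
#' Records missing a modelled covariate cannot be screened and pass through
#' as kept, with a warning. If fewer than four complete records remain, or
#' no covariate is available at all, screening is skipped and everything is
#' kept. A single pass is performed; the screen is not iterated.
#'
#' @param records data frame of dose records (see [read_dose_table()]).
#' @param threshold_rule `"four_times_mean"` or `"four_over_n"`.
#' @return an object of class `"ssd_screen"`: a list with `kept` and
#'   `removed` record data frames (`removed` gains a `cooks_distance`
#'   column), `cooks_distance` for all screened records, `threshold`,
#'   `threshold_rule`, and the fitted screening `model` (or `NULL` when
#'   skipped).
#' @examples
#' screened <- screen_outliers(example_dose_table("curculionidae"))
#' screened$removed$species  # the arbitrarily high 250 Gy record
#' @export
screen_outliers <- function(records,
                            threshold_rule = c("four_times_mean", "four_over_n")) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  skip <- function(msg) {
    warning(msg, "; screening skipped, all records kept", call. = FALSE)
    structure(list(kept = records, removed = records[0, , drop = FALSE],
      cooks_distance = NULL, threshold = NA_real_,
      threshold_rule = threshold_rule, model = NULL), class = "ssd_screen")
  }

  covars <- intersect(c("n_treated", "highest_fail_dose_gy"), names(records))
  covars <- covars[vapply(covars, function(v) any(!is.na(records[[v]])), logical(1))]
  if (length(covars) == 0L) return(skip("no screening covariates available"))

  complete <- complete.cases(records[, covars, drop = FALSE])
  if (sum(complete) < 4L) {
    return(skip("fewer than 4 records with complete screening covariates"))
  }
  if (any(!complete)) {
    warning(sum(!complete), " record(s) missing screening covariates pass",
      " through unscreened", call. = FALSE)
  }

  dat <- records[complete, , drop = FALSE]
  fml <- stats::as.formula(paste("dose_gy ~", paste(covars, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    warning("collinear screening covariates; dropping aliased terms",
      call. = FALSE)
  }
  cd <- cooks.distance(fit)
  threshold <- switch(threshold_rule,
    four_times_mean = 4 * mean(cd),
    four_over_n = 4 / nrow(dat))
  flagged <- which(cd > threshold)

  removed <- dat[flagged, , drop = FALSE]
  removed$cooks_distance <- unname(cd[flagged])
  keep_idx <- setdiff(seq_len(nrow(records)), which(complete)[flagged])
  structure(list(
    kept = records[keep_idx, , drop = FALSE],
    removed = removed,
    cooks_distance = setNames(unname(cd), dat$species),
    threshold = threshold,
    threshold_rule = threshold_rule,
    model = fit
  ), class = "ssd_screen")
}

#' @export
print.ssd_screen <- function(x, ...) {
  cat("Cook's-distance outlier screen (rule: ", x$threshold_rule, ")\n", sep = "")
  if (is.null(x$model)) {
    cat("  screening skipped; all ", nrow(x$kept), " records kept\n", sep = "")
    return(invisible(x))
  }
  cat("  model: ", deparse(stats::formula(x$model)), "\n", sep = "")
  cat("  threshold: ", format(x$threshold, digits = 4), "\n", sep = "")
  cat("  removed ", nrow(x$removed), " of ", nrow(x$kept) + nrow(x$removed),
    " records\n", sep = "")
  if (nrow(x$removed)) {
    for (i in seq_len(nrow(x$removed))) {
      cat("   - ", x$removed$species[i], " (", x$removed$dose_gy[i], " Gy, D = ",
        format(x$removed$cooks_distance[i], digits = 3), ")\n", sep = "")
    }
  }
  invisible(x)
}
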