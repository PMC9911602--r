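## End-to-end pipeline: read -> screen -> combine -> [censor] -> fit ->
## inference -> [bias-correct] -> report.

#' Run the full generic-dose SSD pipeline
#'
#' Chains the package's stages on a raw literature dose table: outlier
#' screening of the raw records (Cook's distance), combination of duplicate
#' records per species (confidence-weighted geometric mean), optional
#' balanced interval-censoring, maximum-likelihood fitting of the candidate
#' SSD families with AICc selection, generic-dose and coverage estimation
#' with optional parametric-bootstrap confidence intervals, and optional
#' Cox-Snell bias correction of the gamma fit.
#'
#' @param input path to a dose-table CSV (see [read_dose_table()]) or a
#'   record data frame.
#' @param taxon label echoed into the report.
#' @param policy an [efficacy_policy()].
#' @param outlier_rule `"four_times_mean"`, `"four_over_n"`, or `"none"`.
#' @param censor logical; fit balanced censored intervals instead of the
#'   combined point doses?
#' @param families SSD families to fit (default all four).
#' @param gd_p coverage levels for generic doses (default 0.90, 0.95, 0.99).
#' @param at_doses candidate doses (Gy) at which to report coverage.
#' @param n_boot bootstrap iterations for confidence intervals; 0 disables
#'   the bootstrap (point estimates only).
#' @param ci_level confidence level in percent.
#' @param seed integer seed for the bootstrap.
#' @param slope_m optional marginal-gain threshold (percent coverage per Gy)
#'   at which to report the slope-criterion dose.
#' @param bias_correct logical; add the Cox-Snell corrected gamma results
#'   (requires the gamma family among the fits).
#' @return object of class `"ssd_report"`: a JSON-serializable list with the
#'   configuration echo, dataset summary (records read, outliers removed,
#'   species combined), the model-comparison table, the selected family and
#'   parameters, generic-dose and coverage estimates (with CIs when
#'   bootstrapped), and optional censoring-summary and bias-correction
#'   tables.
#' @examples
#' rep <- run_ssd_pipeline(example_dose_table("tephritidae"),
#'   taxon = "Tephritidae", at_doses = 150)
#' rep$model_table
#' @export
run_ssd_pipeline <- function(input, taxon = "",
                             policy = efficacy_policy(),
                             outlier_rule = c("four_times_mean", "four_over_n", "none"),
                             censor = FALSE,
                             families = ssd_families(),
                             gd_p = c(0.90, 0.95, 0.99),
                             at_doses = numeric(),
                             n_boot = 0, ci_level = 90, seed = 1,
                             slope_m = NULL, bias_correct = FALSE) {
  outlier_rule <- match.arg(outlier_rule)
  records <- if (is.character(input)) read_dose_table(input) else input
  n_read <- nrow(records)

  screen <- NULL
  kept <- records
  if (outlier_rule != "none") {
    screen <- screen_outliers(records, outlier_rule)
    kept <- screen$kept
  }

  combined <- combine_dose_table(kept, policy)

  censoring <- NULL
  if (censor) {
    # species-level lower bounds: carry the per-record highest failing dose
    # through the combination (maximum over a species' records)
    if ("highest_fail_dose_gy" %in% names(kept)) {
      agg <- tapply(kept$highest_fail_dose_gy, trimws(kept$species),
        function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      combined$highest_fail_dose_gy <- unname(agg[combined$species])
    }
    censoring <- build_balanced_intervals(combined)
    fit_data <- censoring$intervals[, c("lower", "upper")]
  } else {
    fit_data <- combined$dose_gy
  }

  modelset <- ssd_fit(fit_data, families)
  best <- best_fit(modelset)

  make_estimate <- function(statistic, arg) {
    if (n_boot >= 100) {
      est <- ssd_bootstrap(modelset, statistic, arg, n_boot = n_boot,
        level = ci_level, seed = seed)
      list(argument = arg, point = est$point, ci_low = est$ci_low,
        ci_high = est$ci_high, level = ci_level, n_boot = n_boot,
        n_failed = est$n_failed)
    } else {
      point <- switch(statistic, gd = generic_dose(modelset, arg),
        coverage = coverage_at_dose(modelset, arg))
      list(argument = arg, point = point)
    }
  }
  gd <- lapply(gd_p, function(p) make_estimate("gd", p))
  names(gd) <- sprintf("GD%g", 100 * gd_p)
  coverage <- lapply(at_doses, function(d) make_estimate("coverage", d))
  names(coverage) <- sprintf("coverage_at_%g_Gy", at_doses)

  slope_dose <- if (!is.null(slope_m)) {
    dose_at_marginal_gain(modelset, slope_m)
  }

  bias <- NULL
  if (bias_correct) {
    bc <- coxsnell_correct(modelset)
    shifts <- corrected_shift(best_fit(modelset, "gamma"), bc, p = gd_p,
      doses = at_doses)
    bias <- list(corrected_params = as.list(bc$corrected_params),
      bias_vector = as.list(bc$bias_vector), shifts = shifts)
  }

  structure(list(
    config = list(taxon = taxon,
      target_efficacy = policy$target_efficacy,
      retention_confidence = policy$retention_confidence,
      outlier_rule = outlier_rule, censor = censor,
      families = unname(families), gd_p = gd_p, at_doses = at_doses,
      n_boot = n_boot, ci_level = ci_level, seed = seed,
      slope_m = slope_m, bias_correct = bias_correct,
      package_version = as.character(utils::packageVersion("phytoSSD"))),
    dataset = list(records_read = n_read,
      outliers_removed = if (is.null(screen)) 0L else nrow(screen$removed),
      removed = if (is.null(screen)) NULL else
        screen$removed[, intersect(c("species", "dose_gy", "cooks_distance"),
          names(screen$removed))],
      species_combined = nrow(combined)),
    censoring_summary = if (!is.null(censoring)) censoring$summary,
    model_table = summary(modelset),
    best_family = modelset$best,
    best_params = as.list(best$params),
    generic_doses = gd,
    coverage = coverage,
    slope_criterion = if (!is.null(slope_m))
      list(m = slope_m, dose_gy = slope_dose),
    bias_correction = bias,
    modelset = modelset
  ), class = "ssd_report")
}

#' @export
print.ssd_report <- function(x, ...) {
  cat("Generic-dose SSD report", if (nzchar(x$config$taxon))
    paste0(" - ", x$config$taxon), "\n", sep = "")
  cat("  records read: ", x$dataset$records_read,
    "; outliers removed: ", x$dataset$outliers_removed,
    "; species fitted: ", x$dataset$species_combined, "\n", sep = "")
  cat("  selected family: ", x$best_family, "\n", sep = "")
  for (nm in names(x$generic_doses)) {
    e <- x$generic_doses[[nm]]
    cat("  ", nm, ": ", format(e$point, digits = 5), " Gy", sep = "")
    if (!is.null(e$ci_low)) {
      cat(" (", e$level, "% CI ", format(e$ci_low, digits = 5), "-",
        format(e$ci_high, digits = 5), ")", sep = "")
    }
    cat("\n")
  }
  for (nm in names(x$coverage)) {
    e <- x$coverage[[nm]]
    cat("  coverage at ", e$argument, " Gy: ", format(e$point, digits = 4),
      "%", sep = "")
    if (!is.null(e$ci_low)) {
      cat(" (", e$level, "% CI ", format(e$ci_low, digits = 4), "-",
        format(e$ci_high, digits = 4), ")", sep = "")
    }
    cat("\n")
  }
  if (!is.null(x$slope_criterion)) {
    cat("  slope-criterion dose (m = ", x$slope_criterion$m, "%/Gy): ",
      format(x$slope_criterion$dose_gy, digits = 5), " Gy\n", sep = "")
  }
  if (!is.null(x$bias_correction)) {
    cat("  Cox-Snell corrected gamma params: shape ",
      format(x$bias_correction$corrected_params$shape, digits = 5),
      ", scale ", format(x$bias_correction$corrected_params$scale, digits = 5),
      "\n", sep = "")
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes everything in the report except the fitted model object
#' itself; reruns with the same configuration and seed produce an identical
#' file.
#'
#' @param report an `"ssd_report"` from [run_ssd_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ssd_report <- function(report, path) {
  out <- unclass(report)
  out$modelset <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(path)
}

#' Export the fitted SSD curve on a dose grid
#'
#' Evaluates coverage (and, when `n_boot > 0`, a pointwise bootstrap
#' confidence band) on a dose grid, for replotting SSD curves externally.
#'
#' @param fit an `"ssd_fit"` or `"ssd_modelset"`.
#' @param dose_grid doses in Gy (default: 1 Gy steps spanning the data).
#' @param n_boot bootstrap iterations for the band (0 = point curve only).
#' @param ci_level band level in percent.
#' @param seed integer seed.
#' @return data frame with `dose_gy`, `coverage_pct` and, with a band,
#'   `ci_low_pct` / `ci_high_pct`.
#' @export
ssd_curve <- function(fit, dose_grid = NULL, n_boot = 0, ci_level = 90,
                      seed = 1) {
  f <- .check_converged(fit)
  if (is.null(dose_grid)) {
    obs <- if (f$data$kind == "exact") f$data$x else f$data$upper
    dose_grid <- seq(1, ceiling(max(obs) * 1.5), by = 1)
  }
  out <- data.frame(dose_gy = dose_grid,
    coverage_pct = coverage_at_dose(f, dose_grid))
  if (n_boot >= 100) {
    set.seed(seed)
    samples <- matrix(.family_def(f$family)$r(n_boot * f$n_obs, f$params),
      nrow = n_boot)
    curves <- matrix(NA_real_, n_boot, length(dose_grid))
    for (b in seq_len(n_boot)) {
      rf <- tryCatch(.fit_one(f$family, list(kind = "exact", x = samples[b, ])),
        error = function(e) NULL)
      if (!is.null(rf) && rf$converged) {
        curves[b, ] <- coverage_at_dose(rf, dose_grid)
      }
    }
    alpha <- (1 - ci_level / 100) / 2
    out$ci_low_pct <- apply(curves, 2, quantile, alpha, na.rm = TRUE)
    out$ci_high_pct <- apply(curves, 2, quantile, 1 - alpha, na.rm = TRUE)
  }
  out
}
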