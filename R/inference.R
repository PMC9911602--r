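## Generic doses, coverage, bootstrap confidence intervals, slope criterion.

#' Generic dose at a target coverage
#'
#' The generic dose GD_p is the dose at which the fitted SSD's cumulative
#' distribution reaches `p`: the dose estimated to control a proportion `p`
#' of the species in the taxon. It is the phytosanitary analogue of the
#' hazardous concentration HC_5 of ecotoxicology (which uses the lower
#' tail).
#'
#' @param fit an `"ssd_fit"`, `"ssd_modelset"` or `"ssd_bias_corrected"`.
#' @param p target coverage proportion(s) in (0, 1).
#' @return dose(s) in Gy.
#' @examples
#' ms <- ssd_fit(example_dose_table("tephritidae")$dose_gy, "gamma")
#' generic_dose(ms, c(0.90, 0.95, 0.99))
#' @export
generic_dose <- function(fit, p) {
  .check_converged(fit)
  ssd_quantile(fit, p)
}

#' Estimated taxonomic coverage at a candidate dose
#'
#' 100 times the fitted cumulative distribution function at `dose`: the
#' estimated percent of species in the taxon whose required dose does not
#' exceed the candidate generic dose.
#'
#' @param fit an `"ssd_fit"`, `"ssd_modelset"` or `"ssd_bias_corrected"`.
#' @param dose candidate dose(s) in Gy, positive.
#' @return coverage(s) in percent, in \[0, 100\].
#' @export
coverage_at_dose <- function(fit, dose) {
  if (any(!is.finite(dose) | dose <= 0)) {
    stop("dose must be positive", call. = FALSE)
  }
  .check_converged(fit)
  100 * ssd_cdf(fit, dose)
}

.check_converged <- function(fit) {
  f <- if (inherits(fit, "ssd_modelset")) best_fit(fit) else fit
  if (inherits(f, "ssd_fit") && !isTRUE(f$converged)) {
    stop("fit did not converge; refusing to compute inference from it",
      call. = FALSE)
  }
  invisible(f)
}

#' Parametric bootstrap confidence interval for a generic dose or coverage
#'
#' Repeats `n_boot` times: draw `n_obs` doses from the fitted distribution,
#' refit the same family by maximum likelihood, and evaluate the statistic
#' (GD_p for `statistic = "gd"`, percent coverage at a dose for
#' `statistic = "coverage"`). The confidence interval is the percentile
#' interval of the bootstrap replicates. All randomness derives from `seed`
#' (replicate samples are drawn up front, so results are independent of
#' evaluation order); replicates whose refit fails to converge are dropped
#' and counted, with a warning past 10%.
#'
#' Censored fits are bootstrapped by drawing exact samples from the fitted
#' distribution and refitting them as exact data: the censoring is a
#' data-quality artifact of the original records, not part of the fitted
#' species-tolerance model.
#'
#' @param fit an `"ssd_fit"` or `"ssd_modelset"` (selected family used).
#' @param statistic `"gd"` or `"coverage"`.
#' @param arg the coverage proportion `p` (for `"gd"`) or the dose in Gy
#'   (for `"coverage"`).
#' @param n_boot number of bootstrap iterations (default 5000, min 100).
#' @param level confidence level in percent (default 90).
#' @param seed integer seed.
#' @return object of class `"gd_estimate"`: list with `statistic`, `arg`,
#'   `point`, `ci_low`, `ci_high`, `level`, `n_boot`, `n_failed`, `seed`,
#'   and the bootstrap `replicates`.
#' @export
ssd_bootstrap <- function(fit, statistic = c("gd", "coverage"), arg,
                          n_boot = 5000, level = 90, seed = 1) {
  statistic <- match.arg(statistic)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (length(arg) != 1L) stop("arg must be a single value", call. = FALSE)
  f <- .check_converged(fit)
  evaluate <- function(obj) {
    switch(statistic,
      gd = generic_dose(obj, arg),
      coverage = coverage_at_dose(obj, arg))
  }
  point <- evaluate(f)

  set.seed(seed)
  samples <- matrix(.family_def(f$family)$r(n_boot * f$n_obs, f$params),
    nrow = n_boot)
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rf <- tryCatch(.fit_one(f$family, list(kind = "exact", x = samples[b, ])),
      error = function(e) NULL)
    if (!is.null(rf) && rf$converged) reps[b] <- evaluate(rf)
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * n_boot) {
    warning(n_failed, " of ", n_boot, " bootstrap replicates failed to",
      " converge", call. = FALSE)
  }
  alpha <- (1 - level / 100) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(statistic = statistic, arg = arg, point = point,
    ci_low = ci[1], ci_high = ci[2], level = level, n_boot = n_boot,
    n_failed = n_failed, seed = seed, family = f$family,
    replicates = reps), class = "gd_estimate")
}

#' @export
print.gd_estimate <- function(x, digits = 4, ...) {
  lab <- switch(x$statistic,
    gd = paste0("GD", round(100 * x$arg), " (Gy)"),
    coverage = paste0("coverage at ", x$arg, " Gy (%)"))
  cat(lab, ": ", format(x$point, digits = digits), " (", x$level, "% CI: ",
    format(x$ci_low, digits = digits), "-", format(x$ci_high, digits = digits),
    "; ", x$n_boot, " bootstrap iterations",
    if (x$n_failed > 0) paste0(", ", x$n_failed, " failed"), ")\n", sep = "")
  invisible(x)
}

#' Dose beyond which the marginal coverage gain drops below m percent per Gy
#'
#' The slope of the SSD coverage curve at dose `x` is 100 times the fitted
#' density: the percent coverage gained per extra Gy. Raising a generic dose
#' is worthwhile only while that marginal gain exceeds some threshold `m`.
#' This returns the smallest dose at or above the density's mode where
#' `100 * f(dose) < m` (beyond the mode the gain declines monotonically);
#' if the gain is already below `m` at the mode, the mode is returned.
#'
#' @param fit an `"ssd_fit"`, `"ssd_modelset"` or `"ssd_bias_corrected"`.
#' @param m threshold slope in percent coverage per Gy (positive).
#' @return dose in Gy.
#' @export
dose_at_marginal_gain <- function(fit, m) {
  if (!is.finite(m) || m <= 0) stop("m must be positive", call. = FALSE)
  .check_converged(fit)
  upper0 <- ssd_quantile(fit, 1 - 1e-10)
  mode <- optimize(function(x) ssd_density(fit, x), c(1e-9, upper0),
    maximum = TRUE, tol = 1e-9)$maximum
  g <- function(x) 100 * ssd_density(fit, x) - m
  if (g(mode) <= 0) return(mode)
  hi <- mode * 2
  while (g(hi) > 0 && hi < upper0 * 1e6) hi <- hi * 2
  uniroot(g, c(mode, hi), tol = 1e-10)$root
}
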