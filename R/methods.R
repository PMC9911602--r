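## S3 methods for "ssd_fit" and "ssd_modelset".

#' @export
print.ssd_fit <- function(x, digits = 4, ...) {
  cat("SSD fit: ", x$family, " (", x$data_kind, " data, n = ", x$n_obs, ")\n",
    sep = "")
  print(round(x$params, digits))
  cat("logLik ", format(x$loglik, digits = digits),
    ", AICc ", format(x$aicc, digits = digits),
    if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
print.ssd_modelset <- function(x, digits = 4, ...) {
  cat("SSD model set (", x$data_kind, " data, n = ", x$n_obs, ")\n", sep = "")
  print(summary(x), digits = digits)
  invisible(x)
}

#' Model-comparison table for a fitted SSD model set
#'
#' @param object an `"ssd_modelset"`.
#' @param ... unused.
#' @return data frame with one row per family: parameters, log-likelihood,
#'   AIC, AICc, convergence flag and whether the family was selected.
#' @export
summary.ssd_modelset <- function(object, ...) {
  rows <- lapply(object$fits, function(f) {
    data.frame(family = f$family,
      par1 = f$params[1], par2 = f$params[2],
      par_names = paste(names(f$params), collapse = "/"),
      loglik = f$loglik, aic = f$aic, aicc = f$aicc,
      converged = f$converged, best = f$family == object$best,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc), ]
  rownames(out) <- out$family
  out
}

#' @export
coef.ssd_fit <- function(object, ...) object$params

#' @export
coef.ssd_modelset <- function(object, ...) coef(best_fit(object))

#' @export
logLik.ssd_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_obs, class = "logLik")
}

#' @export
logLik.ssd_modelset <- function(object, ...) logLik(best_fit(object))

#' Predict coverage or generic doses from a fitted SSD
#'
#' With `type = "coverage"`, returns the estimated percent of species
#' covered at each dose in `newdata` (100 x fitted CDF). With
#' `type = "dose"`, interprets `newdata` as coverage proportions in (0, 1)
#' and returns the corresponding generic doses (fitted quantiles).
#'
#' @param object an `"ssd_fit"` or `"ssd_modelset"` (selected family used).
#' @param newdata doses in Gy, or proportions for `type = "dose"`.
#' @param type `"coverage"` or `"dose"`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.ssd_fit <- function(object, newdata, type = c("coverage", "dose"), ...) {
  type <- match.arg(type)
  switch(type,
    coverage = coverage_at_dose(object, newdata),
    dose = generic_dose(object, newdata))
}

#' @rdname predict.ssd_fit
#' @export
predict.ssd_modelset <- function(object, newdata, type = c("coverage", "dose"), ...) {
  predict(best_fit(object), newdata, type = match.arg(type), ...)
}

#' @export
simulate.ssd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_obs
  as.data.frame(replicate(nsim, ssd_sample(object, n), simplify = TRUE))
}

#' @export
simulate.ssd_modelset <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(best_fit(object), nsim = nsim, seed = seed, ...)
}

## Quantile residuals: fitted CDF at the observations mapped through the
## standard normal quantile; intervals use their midpoint probability.
#' @export
residuals.ssd_fit <- function(object, ...) {
  dat <- object$data
  p <- if (dat$kind == "exact") {
    ssd_cdf(object, dat$x)
  } else {
    (ssd_cdf(object, dat$lower) + ssd_cdf(object, dat$upper)) / 2
  }
  qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' Plot a fitted SSD curve against the empirical distribution
#'
#' Draws the fitted cumulative coverage curve on a dose grid together with
#' the empirical CDF of the input doses (interval data are shown as
#' horizontal segments between their bounds).
#'
#' @param x an `"ssd_fit"` or `"ssd_modelset"`.
#' @param dose_grid optional vector of doses (Gy) for the curve; defaults to
#'   an even grid spanning the data.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ssd_fit <- function(x, dose_grid = NULL, ...) {
  dat <- x$data
  obs <- if (dat$kind == "exact") dat$x else (dat$lower + dat$upper) / 2
  if (is.null(dose_grid)) {
    dose_grid <- seq(max(min(obs) * 0.25, 1e-6), max(obs) * 1.5, length.out = 400)
  }
  graphics::plot(dose_grid, 100 * ssd_cdf(x, dose_grid), type = "l",
    xlab = "Dose (Gy)", ylab = "Species coverage (%)",
    main = paste("SSD:", x$family), ...)
  n <- length(obs)
  emp <- (rank(obs, ties.method = "first") - 0.5) / n
  if (dat$kind == "exact") {
    graphics::points(obs, 100 * emp, pch = 19, cex = 0.7)
  } else {
    graphics::segments(dat$lower, 100 * emp, dat$upper, 100 * emp)
  }
  invisible(x)
}

#' @export
plot.ssd_modelset <- function(x, ...) plot(best_fit(x), ...)
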