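## Maximum-likelihood SSD fitting for exact and interval-censored doses.

## Normalizes fit input to a canonical list:
##   kind = "exact": x (positive numeric)
##   kind = "interval": lower, upper (positive, lower <= upper)
.as_ssd_data <- function(data) {
  if (is.data.frame(data) || is.matrix(data)) {
    data <- as.data.frame(data)
    cols <- intersect(c("lower", "upper"), names(data))
    if (length(cols) == 2L) {
      lower <- as.numeric(data$lower)
      upper <- as.numeric(data$upper)
    } else if (ncol(data) >= 2L && all(vapply(data[1:2], is.numeric, logical(1)))) {
      lower <- as.numeric(data[[1]])
      upper <- as.numeric(data[[2]])
    } else if ("dose_gy" %in% names(data)) {
      return(list(kind = "exact", x = .check_doses(data$dose_gy)))
    } else {
      stop("interval data needs 'lower' and 'upper' columns", call. = FALSE)
    }
    if (any(!is.finite(lower) | !is.finite(upper) | lower <= 0)) {
      stop("interval bounds must be positive and finite", call. = FALSE)
    }
    if (any(upper < lower)) stop("upper bounds must be >= lower bounds", call. = FALSE)
    return(list(kind = "interval", lower = lower, upper = upper))
  }
  list(kind = "exact", x = .check_doses(as.numeric(data)))
}

.check_doses <- function(x) {
  if (any(!is.finite(x) | x <= 0)) {
    stop("doses must be positive and finite", call. = FALSE)
  }
  x
}

#' Log-likelihood of an SSD family on exact or interval-censored doses
#'
#' Exact doses contribute the log density; a censored species contributes
#' `log(F(upper) - F(lower))`, the log probability that its true required
#' dose lies inside its interval. A degenerate interval (`lower == upper`)
#' contributes the log density at that point, so interval data smoothly
#' reduce to exact data. A zero-probability interval contributes `-Inf`
#' rather than raising an error.
#'
#' @param family SSD family name.
#' @param params length-2 parameter vector (see [ssd_fit()] for
#'   parameterizations).
#' @param data positive numeric vector of doses, or a data frame with
#'   `lower`/`upper` columns of interval bounds (Gy).
#' @return the log-likelihood (scalar).
#' @export
ssd_loglik <- function(family, params, data) {
  family <- .check_family(family)
  params <- .check_params(family, params)
  def <- .family_def(family)
  dat <- .as_ssd_data(data)
  if (dat$kind == "exact") {
    return(sum(def$d(dat$x, params, log = TRUE)))
  }
  degen <- dat$lower == dat$upper
  ll <- 0
  if (any(degen)) ll <- ll + sum(def$d(dat$lower[degen], params, log = TRUE))
  if (any(!degen)) {
    pr <- def$p(dat$upper[!degen], params) - def$p(dat$lower[!degen], params)
    ll <- ll + sum(ifelse(pr > 0, log(pr), -Inf))
  }
  ll
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; all SSD families here have
#' `k = 2` parameters. Returns `Inf` when `n <= k + 1`, where the correction
#' is undefined.
#'
#' @param loglik maximized log-likelihood.
#' @param n_obs number of observations (species).
#' @param k number of estimated parameters (default 2).
#' @return the AICc value.
#' @export
aicc <- function(loglik, n_obs, k = 2) {
  if (n_obs <= k + 1) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

## Exact-data MLEs with closed-form or profile solutions. The lognormal MLE
## is fully closed-form; gamma and Weibull reduce to one monotone scalar
## equation in the shape, solved by uniroot, with the scale profiled out.
## These give the same maximum as the general optimizer, faster and to
## tighter tolerance (important for bootstrap refits).
.mle_exact <- function(family, x) {
  n <- length(x)
  mlx <- mean(log(x))
  switch(family,
    lognormal = c(mlx, sqrt(mean((log(x) - mlx)^2))),
    gamma = {
      # log(a) - digamma(a) = log(mean(x)) - mean(log(x)), decreasing in a
      cval <- log(mean(x)) - mlx
      if (cval <= 0) return(NULL)  # constant data: no interior maximum
      f <- function(a) log(a) - digamma(a) - cval
      a0 <- max(1 / (2 * cval), 1e-6)  # asymptotic log(a)-psi(a) ~ 1/(2a)
      lo <- a0 / 100; hi <- a0 * 100
      while (f(lo) < 0 && lo > 1e-12) lo <- lo / 100
      while (f(hi) > 0 && hi < 1e12) hi <- hi * 100
      if (f(lo) < 0 || f(hi) > 0) return(NULL)
      a <- uniroot(f, c(lo, hi), tol = 1e-12)$root
      c(a, mean(x) / a)
    },
    weibull = {
      # profile equation sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0,
      # increasing in k; powers taken on x/max(x) to avoid overflow
      z <- x / max(x)
      g <- function(k) {
        w <- z^k
        sum(w * log(x)) / sum(w) - 1 / k - mlx
      }
      lo <- 0.01; hi <- 10
      while (g(lo) > 0 && lo > 1e-8) lo <- lo / 10
      while (g(hi) < 0 && hi < 1e6) hi <- hi * 10
      if (g(lo) > 0 || g(hi) < 0) return(NULL)
      k <- uniroot(g, c(lo, hi), tol = 1e-12)$root
      c(k, max(x) * mean(z^k)^(1 / k))
    },
    NULL)
}

## Fits one family; exact data use the closed-form/profile MLE when the
## family has one, otherwise (and for interval data) Nelder-Mead on the
## unconstrained (log) parameter scale. Deterministic given the data
## (moment-matching starts, no randomness).
.fit_one <- function(family, dat) {
  def <- .family_def(family)
  # fully degenerate intervals have the exact-data likelihood, so they take
  # the same closed-form/profile route (keeping the two code paths equal to
  # machine precision)
  x_exact <- if (dat$kind == "exact") dat$x
    else if (all(dat$lower == dat$upper)) dat$lower
  if (!is.null(x_exact)) {
    par <- .mle_exact(family, x_exact)
    if (!is.null(par) && all(is.finite(par)) && all(par > 0)) {
      loglik <- sum(def$d(x_exact, par, log = TRUE))
      if (is.finite(loglik)) {
        return(structure(list(
          family = family,
          params = setNames(par, def$par_names),
          loglik = loglik,
          aic = -2 * loglik + 4,
          aicc = aicc(loglik, length(x_exact)),
          n_obs = length(x_exact),
          converged = TRUE,
          data_kind = dat$kind,
          data = dat
        ), class = "ssd_fit"))
      }
    }
  }
  x_start <- if (dat$kind == "exact") dat$x else (dat$lower + dat$upper) / 2
  start <- def$start(x_start)
  # inlined likelihood: argument validation happens once in the callers,
  # not on every optimizer step
  loglik_at <- if (dat$kind == "exact") {
    function(par) sum(def$d(dat$x, par, log = TRUE))
  } else {
    degen <- dat$lower == dat$upper
    function(par) {
      ll <- 0
      if (any(degen)) ll <- ll + sum(def$d(dat$lower[degen], par, log = TRUE))
      if (any(!degen)) {
        pr <- def$p(dat$upper[!degen], par) - def$p(dat$lower[!degen], par)
        ll <- ll + sum(ifelse(pr > 0, log(pr), -Inf))
      }
      ll
    }
  }
  nll <- function(th) {
    ll <- loglik_at(def$from_opt(th))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- optim(def$to_opt(start), nll, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 10000))
  params <- setNames(def$from_opt(opt$par), def$par_names)
  loglik <- -opt$value
  n_obs <- if (dat$kind == "exact") length(dat$x) else length(dat$lower)
  converged <- opt$convergence == 0 && is.finite(loglik) && loglik > -1e9
  structure(list(
    family = family,
    params = params,
    loglik = loglik,
    aic = -2 * loglik + 4,
    aicc = aicc(loglik, n_obs),
    n_obs = n_obs,
    converged = converged,
    data_kind = dat$kind,
    data = dat
  ), class = "ssd_fit")
}

#' Fit parametric species sensitivity distributions by maximum likelihood
#'
#' Fits each requested family to the per-species doses (or censored dose
#' intervals) by numerical maximum likelihood and selects the family with
#' the lowest small-sample-corrected AIC among converged fits. Ties are
#' broken by the fixed family order gamma, lognormal, loglogistic, weibull,
#' so reruns are deterministic.
#'
#' Parameterizations: lognormal `(meanlog, sdlog)`; log-logistic
#' `(scale, shape)` with CDF `1/(1 + (x/scale)^-shape)`; gamma
#' `(shape, scale)`; Weibull `(shape, scale)`. Optimization runs on the
#' log-transformed parameter scale from moment-matching starting values and
#' uses no randomness.
#'
#' @param data positive numeric vector of per-species doses (Gy), a data
#'   frame with a `dose_gy` column, or a data frame with `lower`/`upper`
#'   columns of censored interval bounds (see [build_balanced_intervals()]).
#' @param families character vector of families to fit; any subset of
#'   `ssd_families()`.
#' @return an object of class `"ssd_modelset"`: a list with `fits` (one
#'   `"ssd_fit"` per family), `best` (name of the selected family), `n_obs`
#'   and `data_kind`. Use [best_fit()] to extract the selected fit and
#'   [generic_dose()] / [coverage_at_dose()] for inference.
#' @examples
#' doses <- example_dose_table("tephritidae")$dose_gy
#' ms <- ssd_fit(doses)
#' ms$best                       # "gamma"
#' generic_dose(ms, 0.95)        # GD95 in Gy
#' @export
ssd_fit <- function(data, families = ssd_families()) {
  families <- vapply(families, .check_family, character(1))
  dat <- .as_ssd_data(data)
  n_obs <- if (dat$kind == "exact") length(dat$x) else length(dat$lower)
  if (n_obs < 3L) stop("at least 3 observations are required", call. = FALSE)
  fits <- lapply(families, .fit_one, dat = dat)
  names(fits) <- families
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) {
    stop("no SSD family converged on these data", call. = FALSE)
  }
  if (any(!conv)) {
    warning("excluding non-converged fits from selection: ",
      paste(families[!conv], collapse = ", "), call. = FALSE)
  }
  # deterministic tie-break: order of ssd_families()
  order_pref <- match(families, ssd_families())
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  aiccs[!conv] <- Inf
  best <- unname(families[order(aiccs, order_pref)][1])
  structure(list(fits = fits, best = best, n_obs = n_obs,
    data_kind = dat$kind, data = dat), class = "ssd_modelset")
}

#' Extract the selected fit from a model set
#'
#' @param object an `"ssd_modelset"` from [ssd_fit()].
#' @param family optional family name to extract instead of the selected one.
#' @return the corresponding `"ssd_fit"`.
#' @export
best_fit <- function(object, family = NULL) {
  stopifnot(inherits(object, "ssd_modelset"))
  if (is.null(family)) return(object$fits[[object$best]])
  family <- .check_family(family)
  fit <- object$fits[[family]]
  if (is.null(fit)) stop("family not fitted: ", family, call. = FALSE)
  fit
}
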