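## Distribution registry for the four SSD candidate families.
##
## All four have positive support and two parameters (k = 2 throughout).
## Parameterizations:
##   lognormal  : meanlog (real), sdlog (> 0)
##   loglogistic: scale (> 0), shape (> 0), CDF F(x) = 1 / (1 + (x/scale)^-shape)
##   gamma      : shape (> 0), scale (> 0)
##   weibull    : shape (> 0), scale (> 0)

#' Candidate SSD families
#'
#' The four two-parameter families fitted by [ssd_fit()], in the fixed
#' order used to break AICc ties.
#'
#' @return character vector of family names.
#' @export
ssd_families <- function() c("gamma", "lognormal", "loglogistic", "weibull")

## log-logistic density/CDF/quantile/random (closed forms; not in base stats)
dllogis_ <- function(x, scale, shape, log = FALSE) {
  out <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  z <- (x[ok] / scale)^shape
  out[ok] <- log(shape / scale) + (shape - 1) * (log(x[ok]) - log(scale)) -
    2 * log1p(z)
  if (log) out else exp(out)
}
pllogis_ <- function(q, scale, shape) {
  out <- numeric(length(q))
  ok <- q > 0
  out[ok] <- 1 / (1 + (q[ok] / scale)^(-shape))
  out
}
qllogis_ <- function(p, scale, shape) scale * (p / (1 - p))^(1 / shape)
rllogis_ <- function(n, scale, shape) qllogis_(runif(n), scale, shape)

## Internal per-family table: d/p/q/r taking a named parameter vector,
## parameter names, transform to/from the unconstrained optimization scale,
## and moment-matching starting values from exact doses.
.family_def <- function(family) {
  switch(family,
    lognormal = list(
      par_names = c("meanlog", "sdlog"),
      d = function(x, par, log = FALSE) dlnorm(x, par[1], par[2], log = log),
      p = function(q, par) plnorm(q, par[1], par[2]),
      q = function(p, par) qlnorm(p, par[1], par[2]),
      r = function(n, par) rlnorm(n, par[1], par[2]),
      to_opt = function(par) c(par[1], log(par[2])),
      from_opt = function(th) c(th[1], exp(th[2])),
      start = function(x) {
        lx <- log(x)
        c(mean(lx), max(sd(lx), 1e-3))
      }
    ),
    loglogistic = list(
      par_names = c("scale", "shape"),
      d = function(x, par, log = FALSE) dllogis_(x, par[1], par[2], log = log),
      p = function(q, par) pllogis_(q, par[1], par[2]),
      q = function(p, par) qllogis_(p, par[1], par[2]),
      r = function(n, par) rllogis_(n, par[1], par[2]),
      to_opt = function(par) log(par),
      from_opt = function(th) exp(th),
      start = function(x) {
        lx <- log(x)
        # logistic on the log scale: sd = pi / (sqrt(3) * shape)
        c(exp(mean(lx)), max(pi / (sqrt(3) * max(sd(lx), 1e-3)), 1e-3))
      }
    ),
    gamma = list(
      par_names = c("shape", "scale"),
      d = function(x, par, log = FALSE) dgamma(x, shape = par[1], scale = par[2], log = log),
      p = function(q, par) pgamma(q, shape = par[1], scale = par[2]),
      q = function(p, par) qgamma(p, shape = par[1], scale = par[2]),
      r = function(n, par) rgamma(n, shape = par[1], scale = par[2]),
      to_opt = function(par) log(par),
      from_opt = function(th) exp(th),
      start = function(x) {
        m <- mean(x)
        v <- max(var(x), 1e-8)
        c(m^2 / v, v / m)
      }
    ),
    weibull = list(
      par_names = c("shape", "scale"),
      d = function(x, par, log = FALSE) dweibull(x, shape = par[1], scale = par[2], log = log),
      p = function(q, par) pweibull(q, shape = par[1], scale = par[2]),
      q = function(p, par) qweibull(p, shape = par[1], scale = par[2]),
      r = function(n, par) rweibull(n, shape = par[1], scale = par[2]),
      to_opt = function(par) log(par),
      from_opt = function(th) exp(th),
      start = function(x) {
        lx <- log(x)
        # Gumbel moments of log(weibull): sd(log x) = pi / (shape * sqrt(6))
        shp <- max(pi / (sqrt(6) * max(sd(lx), 1e-3)), 1e-3)
        c(shp, exp(mean(lx) + 0.5772157 / shp))
      }
    ),
    stop("unknown SSD family: ", family, call. = FALSE)
  )
}

.check_family <- function(family) {
  family <- match.arg(family, ssd_families())
  family
}

.check_params <- function(family, params) {
  def <- .family_def(family)
  if (length(params) != 2L) {
    stop("params must have length 2 (", paste(def$par_names, collapse = ", "),
      ")", call. = FALSE)
  }
  params <- unname(as.numeric(params))
  lower_ok <- if (family == "lognormal") params[2] > 0 else all(params > 0)
  if (!all(is.finite(params)) || !lower_ok) {
    stop("invalid ", family, " parameters", call. = FALSE)
  }
  setNames(params, def$par_names)
}

#' Cumulative distribution, quantile, density and sampling for SSD families
#'
#' Thin wrappers over the four candidate SSD families using the package's
#' fixed parameterizations (see [ssd_fit()]). `x` may be a fitted
#' `"ssd_fit"` object, an `"ssd_modelset"` (its selected family is used), or
#' a family name accompanied by a `params` vector.
#'
#' For a dose `d`, `ssd_cdf()` is the estimated proportion of species in the
#' taxon whose required dose is at most `d`; `ssd_quantile(p)` is the dose at
#' which estimated coverage reaches `p` (the generic dose GD_p, up to the
#' percent scaling).
#'
#' @param x an `"ssd_fit"`, an `"ssd_modelset"`, or a family name
#'   (one of `"gamma"`, `"lognormal"`, `"loglogistic"`, `"weibull"`).
#' @param dose vector of doses (Gy), strictly positive for `ssd_density`.
#' @param p vector of probabilities in (0, 1).
#' @param n number of random draws.
#' @param params named or positional length-2 parameter vector, required when
#'   `x` is a family name.
#' @param log logical; return the log density?
#' @return numeric vector: probabilities for `ssd_cdf`, doses for
#'   `ssd_quantile` and `ssd_sample`, (log) density values for `ssd_density`.
#' @examples
#' ssd_quantile("gamma", 0.95, params = c(shape = 2, scale = 50))
#' ssd_cdf("weibull", 150, params = c(shape = 2.2, scale = 105))
#' @export
ssd_cdf <- function(x, dose, params = NULL) {
  fp <- .resolve_spec(x, params)
  .family_def(fp$family)$p(dose, fp$params)
}

#' @rdname ssd_cdf
#' @export
ssd_quantile <- function(x, p, params = NULL) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  fp <- .resolve_spec(x, params)
  .family_def(fp$family)$q(p, fp$params)
}

#' @rdname ssd_cdf
#' @export
ssd_density <- function(x, dose, params = NULL, log = FALSE) {
  fp <- .resolve_spec(x, params)
  .family_def(fp$family)$d(dose, fp$params, log = log)
}

#' @rdname ssd_cdf
#' @param seed optional integer seed for reproducible sampling.
#' @export
ssd_sample <- function(x, n, params = NULL, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  fp <- .resolve_spec(x, params)
  if (!is.null(seed)) set.seed(seed)
  .family_def(fp$family)$r(n, fp$params)
}

## Accepts fit objects or (family, params) pairs.
.resolve_spec <- function(x, params = NULL) {
  if (inherits(x, "ssd_modelset")) x <- best_fit(x)
  if (inherits(x, "ssd_bias_corrected")) {
    return(list(family = "gamma", params = x$corrected_params))
  }
  if (inherits(x, "ssd_fit")) {
    return(list(family = x$family, params = x$params))
  }
  if (is.character(x) && length(x) == 1L) {
    if (is.null(params)) stop("params required when x is a family name", call. = FALSE)
    family <- .check_family(x)
    return(list(family = family, params = .check_params(family, params)))
  }
  stop("x must be an ssd_fit, ssd_modelset, or family name", call. = FALSE)
}
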