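# Cox-Snell first-order bias correction of the gamma MLE.

test_that("the first-order bias vanishes at exactly rate 1/n", {
  b15 <- coxsnell_bias_gamma(3, 30, 15)
  for (n in c(60, 1000, 1e6)) {
    expect_equal(n * coxsnell_bias_gamma(3, 30, n), 15 * b15,
      tolerance = 1e-12)
  }
  # the O(1/n) bias is negligible against the parameters themselves at huge n
  b <- coxsnell_bias_gamma(3, 30, 1e6)
  expect_lt(abs(b["shape"]) / 3, 1e-5)
  expect_lt(abs(b["scale"]) / 30, 1e-5)
})

test_that("analytic cumulants match numeric differentiation of the expected log-likelihood", {
  # Independent oracle: the per-observation expected gamma log-likelihood
  # under true (a0, s0), as a function of candidate (a, s), is
  #   lambda(a, s) = -a log s - log Gamma(a) + (a-1)(psi(a0) + log s0) - a0 s0 / s,
  # using E[log X] = psi(a0) + log s0 and E[X] = a0 s0. All cumulants the
  # Cordeiro-Klein formula needs are derivatives of lambda, so finite
  # differences of this two-line function give a full numeric replacement
  # for the analytic trigamma/tetragamma expressions.
  lam <- function(th, th0) {
    -th[1] * log(th[2]) - lgamma(th[1]) +
      (th[1] - 1) * (digamma(th0[1]) + log(th0[2])) - th0[1] * th0[2] / th[2]
  }
  hessian_num <- function(fun, x, h) {
    H <- matrix(0, 2, 2)
    for (i in 1:2) {
      e <- c(0, 0); e[i] <- h[i]
      H[i, i] <- (fun(x + e) - 2 * fun(x) + fun(x - e)) / h[i]^2
    }
    e1 <- c(h[1], 0); e2 <- c(0, h[2])
    H[1, 2] <- H[2, 1] <- (fun(x + e1 + e2) - fun(x + e1 - e2) -
      fun(x - e1 + e2) + fun(x - e1 - e2)) / (4 * h[1] * h[2])
    H
  }
  for (theta in list(c(3, 30), c(1.7, 80), c(3.4263, 20.883))) {
    n <- 15
    h <- 1e-3 * theta
    # expected second derivatives at theta (true parameters held fixed)
    kap2 <- n * hessian_num(function(t) lam(t, theta), theta, h)
    # expected third derivatives: difference the Hessian in the candidate
    # parameters only
    kap3 <- array(0, c(2, 2, 2))
    for (l in 1:2) {
      e <- c(0, 0); e[l] <- h[l]
      kap3[, , l] <- n * (hessian_num(function(t) lam(t, theta), theta + e, h) -
        hessian_num(function(t) lam(t, theta), theta - e, h)) / (2 * h[l])
    }
    # total derivative of kappa_ij with respect to the true parameters (the
    # evaluation point and the expectation move together)
    g <- function(t) hessian_num(function(u) lam(u, t), t, h)
    dkap2 <- array(0, c(2, 2, 2))
    for (l in 1:2) {
      e <- c(0, 0); e[l] <- h[l]
      dkap2[, , l] <- n * (g(theta + e) - g(theta - e)) / (2 * h[l])
    }
    bias_num <- phytoSSD:::.coxsnell_bias(-kap2, kap3, dkap2)
    bias_ana <- coxsnell_bias_gamma(theta[1], theta[2], n)
    expect_equal(unname(bias_ana), bias_num, tolerance = 1e-4)
    # the analytic information matrix also matches
    cu <- phytoSSD:::.gamma_cumulants(theta[1], theta[2], n)
    expect_equal(cu$K, -kap2, tolerance = 1e-6)
  }
})

test_that("analytic bias tracks the parametric-bootstrap oracle and correcting shrinks it", {
  # 2000 samples of n = 15 from gamma(shape 3, scale 30): the Monte-Carlo
  # mean of (MLE - truth) estimates the TOTAL bias; the analytic Cox-Snell
  # vector is its O(1/n) leading term, so they agree up to Monte-Carlo error
  # plus the O(1/n^2) remainder (visible at n = 15 on the shape, where a
  # 20,000-replicate run put the total bias near +0.69 against the
  # first-order +0.56; the scale remainder is negligible). The tolerances
  # below cover 3 Monte-Carlo standard errors on top of that remainder; at
  # n = 200 (next block) the remainder is gone and agreement is within pure
  # MC error.
  true <- c(shape = 3, scale = 30)
  n <- 15
  reps <- 2000
  set.seed(91)
  mle <- matrix(NA_real_, reps, 2)
  corrected <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    x <- rgamma(n, true[1], scale = true[2])
    fit <- best_fit(ssd_fit(x, "gamma"), "gamma")
    mle[r, ] <- fit$params
    bc <- tryCatch(coxsnell_correct(fit), error = function(e) NULL)
    if (!is.null(bc)) corrected[r, ] <- bc$corrected_params
  }
  mc_bias <- colMeans(mle) - true
  mc_se <- apply(mle, 2, sd) / sqrt(reps)
  ana <- coxsnell_bias_gamma(true[1], true[2], n)
  expect_lt(abs(ana["shape"] - mc_bias[1]), 0.15 + 3 * mc_se[1])
  expect_lt(abs(ana["scale"] - mc_bias[2]), 0.50 + 3 * mc_se[2])
  # same sign and same order of magnitude, component-wise
  expect_true(all(sign(ana) == sign(mc_bias)))
  expect_true(all(abs(ana) > abs(mc_bias) / 3 & abs(ana) < 3 * abs(mc_bias)))
  # paired comparison on the same datasets: correction shrinks the absolute
  # bias of both parameters
  expect_lt(sum(!complete.cases(corrected)) / reps, 0.01)
  corr_bias <- colMeans(corrected, na.rm = TRUE) - true
  expect_lt(abs(corr_bias[1]), abs(mc_bias[1]))
  expect_lt(abs(corr_bias[2]), abs(mc_bias[2]))
})

test_that("at moderate n the analytic bias matches Monte Carlo within pure MC error", {
  true <- c(shape = 3, scale = 30)
  n <- 200
  reps <- 1500
  set.seed(92)
  mle <- t(replicate(reps, best_fit(ssd_fit(
    rgamma(n, true[1], scale = true[2]), "gamma"), "gamma")$params))
  mc_bias <- colMeans(mle) - true
  mc_se <- apply(mle, 2, sd) / sqrt(reps)
  ana <- coxsnell_bias_gamma(true[1], true[2], n)
  expect_lt(abs(ana["shape"] - mc_bias[1]), 3.5 * mc_se[1])
  expect_lt(abs(ana["scale"] - mc_bias[2]), 3.5 * mc_se[2])
})

test_that("the bias vector is equivariant under rescaling of the doses", {
  b <- coxsnell_bias_gamma(2.5, 40, 12)
  for (const in c(0.1, 3, 25)) {
    bc <- coxsnell_bias_gamma(2.5, 40 * const, 12)
    expect_equal(bc["shape"], b["shape"], tolerance = 1e-12)
    expect_equal(unname(bc["scale"]), unname(const * b["scale"]),
      tolerance = 1e-12)
  }
})

test_that("correction at huge n leaves the MLE essentially unchanged", {
  set.seed(93)
  x <- rgamma(1e6, 3, scale = 30)
  fit <- best_fit(ssd_fit(x, "gamma"), "gamma")
  bc <- coxsnell_correct(fit)
  expect_equal(unname(bc$corrected_params / fit$params), c(1, 1),
    tolerance = 1e-4)
})

test_that("guards reject unusable fits and degenerate corrections", {
  ms <- ssd_fit(tephritidae$dose_gy)
  expect_error(coxsnell_correct(best_fit(ms, "weibull")), "gamma family")
  small <- structure(list(family = "gamma", params = c(shape = 2, scale = 30),
    converged = TRUE, n_obs = 3), class = "ssd_fit")
  expect_error(coxsnell_correct(small), "at least 4")
  expect_error(coxsnell_bias_gamma(-1, 2, 10), "positive")
})

test_that("corrected_shift reports leftward GD shifts and coverage gains consistently", {
  ms <- ssd_fit(tephritidae$dose_gy, "gamma")
  fit <- best_fit(ms, "gamma")
  bc <- coxsnell_correct(ms)
  tab <- corrected_shift(ms, bc, p = c(0.9, 0.95, 0.99), doses = c(150, 175))
  gd <- tab[tab$quantity == "gd_shift_gy", ]
  cov <- tab[tab$quantity == "coverage_gain_pp", ]
  # shift columns are exactly the stated differences of the other two
  expect_equal(gd$shift, gd$crude - gd$corrected, tolerance = 1e-12)
  expect_equal(cov$shift, cov$corrected - cov$crude, tolerance = 1e-12)
  # entries recompute from the two fits directly
  expect_equal(gd$crude, generic_dose(fit, c(0.9, 0.95, 0.99)),
    tolerance = 1e-10)
  expect_equal(gd$corrected, generic_dose(bc, c(0.9, 0.95, 0.99)),
    tolerance = 1e-10)
  expect_equal(cov$corrected, coverage_at_dose(bc, c(150, 175)),
    tolerance = 1e-10)
  # the correction shrinks the fitted spread: SSD shifts left in the upper
  # tail (smaller GDs) and coverage at candidate doses rises
  expect_true(all(gd$shift > 0))
  expect_true(all(cov$shift > 0))
})
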