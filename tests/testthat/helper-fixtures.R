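# Shared fixtures and small oracles used across test files.

curculionidae <- example_dose_table("curculionidae")
tephritidae <- example_dose_table("tephritidae")

# Brute-force Cook's distance: delete each observation, refit, and measure
# the scaled shift in fitted values. Independent of stats::cooks.distance.
cooks_by_deletion <- function(formula, data) {
  full <- lm(formula, data = data)
  yhat <- fitted(full)
  p <- length(coef(full))
  s2 <- sum(residuals(full)^2) / (nrow(data) - p)
  vapply(seq_len(nrow(data)), function(i) {
    fi <- lm(formula, data = data[-i, , drop = FALSE])
    yhat_i <- predict(fi, newdata = data)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}

# Random admissible per-species dose table for censoring property tests.
random_species_doses <- function(n, seed) {
  set.seed(seed)
  dose <- exp(runif(n, log(30), log(250)))
  has_fail <- runif(n) < 0.6
  fail <- ifelse(has_fail, dose * runif(n, 0.3, 0.95), NA_real_)
  data.frame(species = sprintf("sp%02d", seq_len(n)), dose_gy = dose,
    confidence = runif(n, 0.01, 0.99), highest_fail_dose_gy = fail,
    stringsAsFactors = FALSE)
}
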