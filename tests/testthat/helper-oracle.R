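# Independent oracles kept deliberately separate from the package internals.

# Brute-force grid search over (log_ed50, hill) minimizing the residual sum
# of squares of the constrained sigmoid. Returns the best grid point and its
# objective. The prediction formula is written out directly rather than
# calling the package.
grid_ed50_oracle <- function(dose, pct,
                             log_grid = seq(-2, 2, by = 0.01),
                             hill_grid = seq(0.1, 5, by = 0.05)) {
  logd <- log10(dose)
  best <- list(ssr = Inf, log_ed50 = NA, hill = NA)
  for (h in hill_grid) {
    # vectorized over the log_ed50 grid: pred is |grid| x |data|
    pred <- 100 / (1 + 10^(h * outer(log_grid, logd, "-")))
    ssr <- rowSums(sweep(pred, 2, pct, "-")^2)
    i <- which.min(ssr)
    if (ssr[i] < best$ssr) {
      best <- list(ssr = ssr[i], log_ed50 = log_grid[i], hill = h)
    }
  }
  best
}

ssr_sigmoid <- function(dose, pct, log_ed50, hill) {
  pred <- 100 / (1 + 10^(hill * (log_ed50 - log10(dose))))
  sum((pct - pred)^2)
}

# Monte-Carlo oracle for the additive-ED50 interval: resample the component
# ED50s from independent normals and read the 2.5/97.5 percentiles of
# f*A + (1-f)*B.
mc_additive_ci <- function(f, ed50_a, se_a, ed50_b, se_b, n = 1e5,
                           seed = 123) {
  set.seed(seed)
  z <- f * rnorm(n, ed50_a, se_a) + (1 - f) * rnorm(n, ed50_b, se_b)
  unname(quantile(z, c(0.025, 0.975)))
}
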