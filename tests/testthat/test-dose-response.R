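test_that("predict_inhibition matches the closed-form constrained sigmoid", {
  # midpoint: exactly 50 at the ED50, any hill
  for (h in c(0.5, 1, 1.5, 3)) {
    expect_equal(predict_inhibition(2.3, log10(2.3), h), 50)
  }
  # closed form: log_ed50 = 0, hill = 1, dose = 10 -> 100/(1 + 10^-1)
  expect_equal(predict_inhibition(10, 0, 1), 100 / 1.1, tolerance = 1e-12)
  # asymptotes
  expect_gt(predict_inhibition(1e8, 0, 1), 99.99)
  expect_lt(predict_inhibition(1e-8, 0, 1), 0.01)
  expect_error(predict_inhibition(-1, 0, 1), "positive")
  expect_error(predict_inhibition(1, 0, -1), "hill")
})

test_that("fit_ed50 recovers exact parameters from noise-free data", {
  d <- rep(c(0.3, 1, 3, 10), each = 2)
  y <- predict_inhibition(d, log10(2.3), 1.5)
  fit <- fit_ed50(d, y)
  expect_true(fit$converged)
  expect_equal(fit$ed50, 2.3, tolerance = 1e-4)
  expect_equal(fit$hill, 1.5, tolerance = 1e-4)
})

test_that("fit_ed50 requires at least 3 distinct positive doses", {
  expect_error(fit_ed50(c(1, 1, 2, 2), c(10, 20, 60, 70)), "3 distinct")
  expect_error(fit_ed50(c(0, 1, 3), c(0, 30, 70)), "positive")
})

test_that("fitter is at least as good as a brute-force grid oracle", {
  set.seed(21)
  for (i in 1:8) {
    true_le <- runif(1, -0.5, 0.8)
    true_h <- runif(1, 0.8, 2.5)
    d <- rep(10^true_le * c(0.15, 0.5, 2, 7), each = 4)
    y <- predict_inhibition(d, true_le, true_h) + rnorm(length(d), 0, 12)
    fit <- fit_ed50(d, y)
    oracle <- grid_ed50_oracle(d, y)
    ssr_fit <- ssr_sigmoid(d, y, fit$log_ed50, fit$hill)
    # continuous optimum must not lose to the grid by more than one grid step
    step_obj <- ssr_sigmoid(d, y, oracle$log_ed50 + 0.01, oracle$hill) -
      oracle$ssr
    expect_lte(ssr_fit, oracle$ssr + abs(step_obj) + 1e-6)
    # agreement within a couple of grid steps on log_ed50
    expect_lt(abs(fit$log_ed50 - oracle$log_ed50), 0.025)
  }
})

test_that("dose rescaling shifts log_ed50 and leaves hill and residuals alone", {
  set.seed(31)
  d <- rep(c(0.3, 1, 3, 10), each = 4)
  y <- predict_inhibition(d, log10(2.3), 1.5) + rnorm(length(d), 0, 10)
  base <- fit_ed50(d, y)
  for (k in c(0.1, 2, 50)) {
    scaled <- fit_ed50(k * d, y)
    expect_equal(scaled$log_ed50, base$log_ed50 + log10(k), tolerance = 1e-5)
    expect_equal(scaled$hill, base$hill, tolerance = 1e-5)
    expect_equal(scaled$residual_sd, base$residual_sd, tolerance = 1e-6)
  }
})

test_that("row permutation leaves the fit bit-identical", {
  set.seed(41)
  d <- rep(c(0.3, 1, 3, 10), each = 4)
  y <- predict_inhibition(d, log10(2.3), 1.5) + rnorm(length(d), 0, 10)
  perm <- sample(length(d))
  f1 <- fit_ed50(d, y)
  f2 <- fit_ed50(d[perm], y[perm])
  expect_identical(f1$log_ed50, f2$log_ed50)
  expect_identical(f1$hill, f2$hill)
  expect_identical(f1$ci95, f2$ci95)
})

test_that("CI brackets the estimate and narrows with more animals per dose", {
  widths <- vapply(c(4, 16, 64), function(n) {
    set.seed(100 + n)
    reps <- vapply(1:12, function(i) {
      d <- rep(c(0.3, 1, 3, 10), each = n)
      y <- predict_inhibition(d, log10(2.3), 1.5) + rnorm(length(d), 0, 15)
      f <- fit_ed50(d, y)
      expect_true(f$ci95[["lower"]] < f$ed50 && f$ed50 < f$ci95[["upper"]])
      f$ci95[["upper"]] - f$ci95[["lower"]]
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("fit_arm fits on total mixture dose from a percent-inhibition table", {
  cfg_a <- generator_config(seed = 61, true_ed50 = 27.8, drug = "atomoxetine")
  cfg_b <- generator_config(seed = 61, true_ed50 = 2.3, drug = "morphine")
  dat <- gen_fixed_ratio(cfg_a, cfg_b, ratio = 3)
  tb <- percent_inhibition_table(dat)
  combo <- tb[tb$arm == "atomoxetine+morphine", ]
  expect_equal(combo$total_dose_mg_kg,
               combo$dose1_mg_kg + combo$dose2_mg_kg)
  fit <- fit_arm(tb, "atomoxetine+morphine")
  expect_s3_class(fit, "dose_response_fit")
  expect_true(fit$converged)
  expect_error(fit_arm(tb, "absent-arm"), "no dosed animals")
})
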