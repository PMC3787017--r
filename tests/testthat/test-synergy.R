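test_that("fractional_multiplier evaluates the printed formula and its limits", {
  expect_equal(fractional_multiplier(3, 27.8, 2.3), 3 / (3 + 27.8 / 2.3),
               tolerance = 1e-12)
  expect_equal(fractional_multiplier(3, 27.8, 2.3), 0.1988473, tolerance = 1e-6)
  expect_equal(fractional_multiplier(0, 5, 9), 0)       # pure drug B
  expect_equal(fractional_multiplier(Inf, 5, 9), 1)     # pure drug A limit
  expect_error(fractional_multiplier(3, -1, 2), "> 0")
})

test_that("additive_ed50 is bracketed by the component ED50s and symmetric under relabeling", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0.5, 50); b <- runif(1, 0.5, 50); r <- runif(1, 0.05, 20)
    z_ab <- additive_ed50(fractional_multiplier(r, a, b), a, b)
    expect_gte(z_ab, min(a, b) - 1e-12)
    expect_lte(z_ab, max(a, b) + 1e-12)
    # relabeling A <-> B with ratio 1/r gives the same additive point
    z_ba <- additive_ed50(fractional_multiplier(1 / r, b, a), b, a)
    expect_equal(z_ab, z_ba, tolerance = 1e-10)
  }
  # equal-potency identity
  expect_equal(additive_ed50(0.37, 4, 4), 4)
  expect_error(additive_ed50(1.2, 4, 4), "\\[0, 1\\]")
})

test_that("additive ED50 moves monotonically from ED50_B to ED50_A as the ratio grows", {
  a <- 27.8; b <- 2.3
  ratios <- 10^seq(-3, 3, length.out = 100)
  z <- vapply(ratios, function(r) {
    additive_ed50(fractional_multiplier(r, a, b), a, b)
  }, numeric(1))
  expect_true(all(diff(z) > 0))
  expect_equal(z[1], b, tolerance = 0.01)
  expect_equal(z[length(z)], a, tolerance = 0.5)
})

test_that("additive ED50s for the 3:1 and 10:1 mixtures match the published values", {
  z3 <- additive_ed50(fractional_multiplier(3, 27.8, 2.3), 27.8, 2.3)
  z10 <- additive_ed50(fractional_multiplier(10, 27.8, 2.3), 27.8, 2.3)
  expect_equal(round(z3, 1), 7.4)
  expect_equal(round(z10, 1), 13.8)
})

test_that("additive_ed50_ci agrees with a Monte-Carlo resampling oracle", {
  f <- fractional_multiplier(3, 27.8, 2.3)
  fit_a <- atx_alone()   # 27.8 (22-36)
  fit_b <- mor_alone()   # 2.3 (2.0-2.5)
  ci <- additive_ed50_ci(f, fit_a, fit_b)
  se_a <- mean(c(36 - 27.8, 27.8 - 22)) / 1.96
  se_b <- mean(c(2.5 - 2.3, 2.3 - 2.0)) / 1.96
  mc <- mc_additive_ci(f, 27.8, se_a, 2.3, se_b)
  expect_equal(unname(ci[1]), mc[1], tolerance = 0.02)
  expect_equal(unname(ci[2]), mc[2], tolerance = 0.02)
  # degenerate and limit cases
  exact_a <- ed50_estimate(27.8, 27.8 - 1e-9, 27.8 + 1e-9)
  exact_b <- ed50_estimate(2.3, 2.3 - 1e-9, 2.3 + 1e-9)
  degenerate <- additive_ed50_ci(f, exact_a, exact_b)
  expect_equal(unname(degenerate), rep(additive_ed50(f, 27.8, 2.3), 2),
               tolerance = 1e-6)
  only_b <- additive_ed50_ci(0, fit_a, fit_b)
  expect_equal(unname(only_b), 2.3 + c(-1, 1) * 1.96 * se_b, tolerance = 1e-9)
  # missing component CI -> indeterminate (NA interval)
  no_ci <- ed50_estimate(5)
  expect_true(all(is.na(additive_ed50_ci(f, no_ci, fit_b))))
})

test_that("isobologram verdicts reproduce the published fixed-ratio outcomes", {
  # 3:1 combination: observed 2.4 (2.0-3.0) vs additive CI 6.3-8.2
  expect_equal(isobologram_verdict(c(2.0, 3.0), c(6.3, 8.2)), "synergistic")
  # 10:1 combination: observed 7.8 (6.6-9.2) vs additive CI 11.2-17.8
  expect_equal(isobologram_verdict(c(6.6, 9.2), c(11.2, 17.8)), "synergistic")
  # overlap -> additive; reversed -> antagonistic; NA -> indeterminate
  expect_equal(isobologram_verdict(c(6, 9), c(7, 12)), "additive")
  expect_equal(isobologram_verdict(c(13, 20), c(7, 12)), "antagonistic")
  expect_equal(isobologram_verdict(c(NA, 9), c(7, 12)), "indeterminate")
  # touching bounds count as overlap
  expect_equal(isobologram_verdict(c(5, 7), c(7, 12)), "additive")
})

test_that("isobologram() assembles F, additive point and interaction index", {
  obs <- ed50_estimate(2.4, 2.0, 3.0, label = "3:1 mixture")
  iso <- isobologram(atx_alone(), mor_alone(), obs, ratio = 3)
  expect_s3_class(iso, "isobologram_result")
  expect_equal(iso$f, fractional_multiplier(3, 27.8, 2.3))
  expect_equal(round(iso$z_add, 1), 7.4)
  expect_equal(iso$interaction_index, 2.4 / iso$z_add)
  expect_equal(iso$verdict, "synergistic")
})

test_that("fixed-dose CI-shift test reproduces the published comparisons", {
  mor <- mor_alone()  # 2.3 (2.0-2.5)
  # +atomoxetine 10 mg/kg: 0.6 (0.4-0.8) -> significant leftward shift
  expect_equal(fixed_dose_shift(mor, ed50_estimate(0.6, 0.4, 0.8)),
               "significant_leftward")
  # +duloxetine 5 mg/kg: 2.0 (1.3-3.0) -> overlapping CIs, no shift
  expect_equal(fixed_dose_shift(mor, ed50_estimate(2.0, 1.3, 3.0)),
               "no_shift")
  # a fit compared with itself
  expect_equal(fixed_dose_shift(mor, mor), "no_shift")
  # rightward mirror and missing-CI cases
  expect_equal(fixed_dose_shift(mor, ed50_estimate(5, 4, 6)),
               "significant_rightward")
  expect_equal(fixed_dose_shift(mor, ed50_estimate(5)), "indeterminate")
})
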