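test_that("initial_rate is the OLS slope, floored at zero", {
  expect_equal(initial_rate(0:3, c(0, 10, 20, 30)), 10)
  expect_equal(initial_rate(c(0, 3), c(5, 5)), 0)
  # least-squares slope by hand: cov/var = 51/5
  expect_equal(initial_rate(0:3, c(0, 9, 21, 30)), 10.2)
  expect_warning(v <- initial_rate(0:3, c(30, 20, 10, 0)), "floored")
  expect_equal(v, 0)
  # origin-constrained variant
  expect_equal(initial_rate(0:3, c(0, 10, 20, 30), origin = TRUE), 10)
  expect_error(initial_rate(1, 5), ">= 2")
})

test_that("occupancy_percent is the vehicle-normalized rate deficit", {
  veh <- c(9, 10, 11)
  expect_equal(occupancy_percent(10, veh), 0)
  expect_equal(occupancy_percent(0, veh), 100)
  expect_equal(occupancy_percent(5, veh), 50)
  # scale invariance: rescaling all signals by c > 0 cancels
  set.seed(5)
  for (i in 1:20) {
    v <- runif(1, 0, 20); k <- runif(1, 0.1, 10)
    expect_equal(occupancy_percent(k * v, k * veh), occupancy_percent(v, veh))
  }
  expect_error(occupancy_percent(5, numeric(0)), "non-empty")
  expect_error(occupancy_percent(5, c(0, 0)), "> 0")
  # archival literal form is not scale-invariant but is available
  expect_equal(occupancy_percent(0.5, c(1, 1), literal = TRUE), 50)
})

test_that("summarize_occupancy reports mean and SEM per arm and transporter", {
  occ <- data.frame(
    arm = c("drug", "drug", "drug", "veh"),
    transporter = "NET",
    occupancy_pct = c(80, 84, 82, 50)
  )
  s <- summarize_occupancy(occ)
  drug <- s[s$arm == "drug", ]
  expect_equal(drug$mean_occupancy_pct, 82)
  expect_equal(drug$sem_occupancy_pct, 2 / sqrt(3), tolerance = 1e-9)
  veh <- s[s$arm == "veh", ]
  expect_equal(veh$mean_occupancy_pct, 50)
  expect_true(is.na(veh$sem_occupancy_pct))
})

test_that("synthetic round-trip recovers the generating occupancy", {
  cfg <- generator_config(seed = 17, true_ed50 = 1, n_per_group = 100)
  b <- gen_binding(cfg, c(treated = 82), transporter = "NET")
  s <- summarize_occupancy(occupancy_table(b))
  treated <- s[s$arm == "treated", ]
  expect_lt(abs(treated$mean_occupancy_pct - 82),
            2 * treated$sem_occupancy_pct)
  veh <- s[s$arm == "vehicle", ]
  expect_lt(abs(veh$mean_occupancy_pct), 2 * veh$sem_occupancy_pct + 1e-9)
})

test_that("occupancy_table normalizes per session by default, pooled on request", {
  mk <- function(session, arm, slope, id) {
    data.frame(session = session, animal_id = id, arm = arm,
               transporter = "NET", time_min = 0:3, signal = 2 + slope * (0:3))
  }
  d <- binding_data(rbind(
    mk("S1", "vehicle", 10, "v1"), mk("S1", "drug", 5, "t1"),
    mk("S2", "vehicle", 20, "v2"), mk("S2", "drug", 5, "t2")
  ))
  per_sess <- occupancy_table(d)
  expect_equal(per_sess$occupancy_pct[per_sess$animal_id == "t1"], 50)
  expect_equal(per_sess$occupancy_pct[per_sess$animal_id == "t2"], 75)
  pooled <- occupancy_table(d, per_session = FALSE)
  expect_equal(pooled$occupancy_pct[pooled$animal_id == "t1"],
               100 * (1 - 5 / 15))
  expect_error(occupancy_table(d, vehicle_arm = "none"), "cannot normalize")
})

test_that("binding_data validation rejects malformed time courses", {
  bad <- data.frame(session = "S1", animal_id = "a", arm = "vehicle",
                    transporter = "DAT", time_min = 0:3, signal = 1:4)
  expect_error(binding_data(bad), "NET")
  one_point <- data.frame(session = "S1", animal_id = "a", arm = "vehicle",
                          transporter = "NET", time_min = 0, signal = 1)
  expect_error(binding_data(one_point), "fewer than 2")
})
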