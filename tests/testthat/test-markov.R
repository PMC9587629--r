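test_that("forced and degenerate schedules give the expected occupancy", {
  # certain death in cycle 1: half-cycle alive credit is exactly 0.5
  sch <- transition_schedule(56, horizon = 1, q = 1, cvd_incidence = 0)
  tr <- run_cohort(sch, "non_cvd", 1)
  expect_equal(sum(tr$half_cycle[1, c("non_cvd", "cvd")]), 0.5)

  # immortal cohort stays fully alive
  sch0 <- transition_schedule(56, horizon = 20, q = rep(0, 20),
                              cvd_incidence = 0)
  tr0 <- run_cohort(sch0, "non_cvd", 20)
  expect_equal(unname(tr0$occupancy[, "non_cvd"]), rep(1, 21))
})

test_that("three-cycle trace matches the hand-computed values", {
  q <- c(0.1, 0.2, 0.3)
  sch <- transition_schedule(56, horizon = 3, q = q, hazard_ratio = 1,
                             cvd_incidence = 0)
  tr <- run_cohort(sch, "non_cvd", 3)
  expect_equal(unname(tr$occupancy[, "non_cvd"]),
               c(1, 0.9, 0.72, 0.504))
  expect_equal(unname(tr$half_cycle[, "non_cvd"]),
               c(0.95, 0.81, 0.612))
  oracle <- brute_force_trace(q, q, rep(0, 3), "non_cvd", 3)
  expect_equal(unname(tr$occupancy), unname(oracle))
})

test_that("matrix engine equals the brute-force scalar loop on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    q <- runif(5, 0, 0.9)
    hr <- runif(1, 0.5, 3)
    inc <- runif(5, 0, 0.3)
    start <- sample(c("non_cvd", "cvd"), 1)
    sch <- transition_schedule(60, horizon = 5, q = q, hazard_ratio = hr,
                               cvd_incidence = inc)
    tr <- run_cohort(sch, start, 5)
    oracle <- brute_force_trace(q, pmin(1 - (1 - q)^hr, 1), inc, start, 5)
    expect_equal(unname(tr$occupancy), unname(oracle), tolerance = 1e-12)
    # occupancy conservation and absorbing death
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 6),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
})

test_that("schedule shorter than the horizon is an explicit error", {
  sch <- transition_schedule(56, horizon = 5)
  expect_error(run_cohort(sch, "non_cvd", 10), "missing ages")
  expect_error(transition_schedule(56, horizon = 5, q = c(0.1, 0.2)),
               "length")
})

test_that("discounted QALYs match closed forms on an immortal cohort", {
  sch <- transition_schedule(56, horizon = 10, q = rep(0, 10),
                             cvd_incidence = 0)
  tr <- run_cohort(sch, "non_cvd", 10)
  u <- c(non_cvd = 1, cvd = 1)
  expect_equal(discounted_qalys(tr, u, discount_rate = 0), 10)
  expect_equal(discounted_qalys(tr, u, discount_rate = 0.04),
               sum(1 / 1.04^(1:10)))
  expect_equal(discounted_qalys(tr, u, 0.04, discount_from_cycle = 0),
               sum(1 / 1.04^(0:9)))
  expect_error(discounted_qalys(tr, c(non_cvd = 1.2, cvd = 1), 0.04),
               "\\[0, 1\\]")
})

test_that("discounted QALYs strictly decrease in the discount rate", {
  sch <- transition_schedule(56, horizon = 30)
  tr <- run_cohort(sch, "non_cvd", 30)
  u <- c(non_cvd = 0.9, cvd = 0.8)
  q <- vapply(c(0, 0.02, 0.04, 0.08), function(r) discounted_qalys(tr, u, r),
              numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("hazard ratio 1 with equal utilities removes the state labels", {
  p <- default_parameters()
  p$markov$hazard_ratio <- 1
  p$utility$state_utilities <- list(non_cvd = 0.85, cvd = 0.85)
  expect_equal(remaining_qalys(56, TRUE, p), remaining_qalys(56, FALSE, p))
})

test_that("half-cycle QALYs lie strictly between the start- and end-of-cycle variants", {
  sch <- transition_schedule(56, horizon = 40)
  tr <- run_cohort(sch, "non_cvd", 40)
  u <- c(non_cvd = 0.87, cvd = 0.80, dead = 0)
  r <- 0.04
  w <- 1 / 1.04^(1:40)
  start_occ <- tr$occupancy[1:40, ] %*% u
  end_occ <- tr$occupancy[2:41, ] %*% u
  hc <- discounted_qalys(tr, u[1:2], r)
  expect_lt(hc, sum(start_occ * w))
  expect_gt(hc, sum(end_occ * w))
})

test_that("calibration reproduces the remaining-QALY targets", {
  cal <- calibrate_schedules()
  expect_lt(abs(cal$achieved[1] - 13.3), 0.05)
  expect_lt(abs(cal$achieved[2] - 11.1), 0.05)
  expect_equal(remaining_qalys(56, FALSE, cal$params), cal$achieved[1])
  expect_equal(remaining_qalys(56, TRUE, cal$params), cal$achieved[2])
  expect_gt(cal$achieved[1], cal$achieved[2])
})

test_that("calibration to the uncalibrated output is (near-)identity", {
  p <- default_parameters()
  t1 <- remaining_qalys(56, FALSE, p)
  t2 <- remaining_qalys(56, TRUE, p)
  cal <- calibrate_schedules(targets = c(t1, t2), params = p)
  expect_equal(cal$mortality_scale, 1, tolerance = 1e-4)
  expect_equal(cal$utility_scale, 1, tolerance = 1e-4)
})

test_that("infeasible calibration targets fail with diagnostics", {
  expect_error(calibrate_schedules(targets = c(200, 150)),
               "calibration failure")
  expect_error(calibrate_schedules(targets = c(11, 13)), "must not exceed")
})
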