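test_that("expected ambulance cost reproduces the published cells", {
  expect_equal(round(expected_ambulance_cost(0.29, 559)), 162)
  expect_equal(expected_ambulance_cost(0, 559), 0)
  expect_equal(round(expected_ambulance_cost(0.75, 559)), 419)
  expect_equal(round(expected_ambulance_cost(0.90, 559)), 503)
  expect_error(expected_ambulance_cost(1.2, 559), "probability")
})

test_that("algorithm add-on cost is 192 by wages and 230 by tariffs", {
  sc <- default_scenarios()
  base <- primary_addon_cost(sc$base)
  expect_equal(base$total, 192)
  expect_equal(unname(base$breakdown),  c(41, 99, 52))
  expect_equal(primary_addon_cost(sc$cons)$total, 230)

  zeroed <- load_parameters(list(cost = list(
    algorithm_lab_cost = 0, personnel_cost_wage = 0,
    outpatient_referral_cost = 0
  )))
  expect_equal(primary_addon_cost(resolve_scenario(zeroed, "base_case"))$total,
               0)
})

test_that("mean DRG cost divides total expenditure by cohort size", {
  expect_equal(drg_mean_cost(840664, 567), 1483)
  expect_equal(drg_mean_cost(1000, 1), 1000)
  expect_equal(drg_mean_cost(840664, 100), 8407)
  expect_error(drg_mean_cost(840664, 0), "positive")
})

test_that("strategy totals equal the published table and sum their components", {
  sc <- default_scenarios()
  pb <- strategy_total_cost(sc$base, "primary_care_algorithm")
  hb <- strategy_total_cost(sc$base, "hospital_standard")
  pc <- strategy_total_cost(sc$cons, "primary_care_algorithm")
  hc <- strategy_total_cost(sc$cons, "hospital_standard")
  expect_equal(pb$total, 520)   # 162 + 166 + 192
  expect_equal(hb$total, 2314)  # 162 + 166 + 503 + 1483
  expect_equal(pc$total, 558)
  expect_equal(hc$total, 2230)  # 162 + 166 + 419 + 1483
  for (x in list(pb, hb, pc, hc)) {
    expect_equal(x$total, sum(x$components$expected))
  }
  # hospital arm with ambulance probability forced to zero
  p0 <- load_parameters(list(cost = list(p_ambulance_to_hospital_base = 0)))
  h0 <- strategy_total_cost(resolve_scenario(p0, "base_case"),
                            "hospital_standard")
  expect_equal(h0$total, 162 + 166 + 0 + 1483)
})

test_that("strategy totals are monotone in unit costs and probabilities", {
  base <- default_scenarios()$base
  ref <- strategy_total_cost(base, "hospital_standard")$total
  bump <- function(overrides) {
    p <- load_parameters(overrides)
    strategy_total_cost(resolve_scenario(p, "base_case"),
                        "hospital_standard")$total
  }
  expect_gte(bump(list(cost = list(ems_cost_per_transport = 600))), ref)
  expect_gte(bump(list(cost = list(p_ambulance_to_hospital_base = 0.95))), ref)
  expect_gte(bump(list(cost = list(drg_total = 900000))), ref)
  expect_lte(bump(list(cost = list(consultation_cost = 100))), ref)
})

test_that("shared components cancel exactly in the incremental cost", {
  for (shift in c(-50, 0, 117)) {
    p <- load_parameters(list(cost = list(consultation_cost = 166 + shift)))
    sc <- resolve_scenario(p, "base_case")
    d <- strategy_total_cost(sc, "primary_care_algorithm")$total -
      strategy_total_cost(sc, "hospital_standard")$total
    expect_equal(d, -1794)
  }
})

test_that("bottom-up record costing matches the analytic tree within 3 SE", {
  spec <- cohort_spec("hospital", n = 50000, seed = 3, p_ambulance = 0.90)
  coh <- generate_cohort(spec)
  res <- cost_from_records(coh, list(ems_cost_per_transport = 559))
  analytic <- 0.90 * 559 + 1483  # non-shared hospital components, unrounded
  expect_lt(abs(res$mean_cost - analytic), 3 * res$se)

  one <- coh[1, ]
  one$ambulance <- FALSE
  one$cost_eur <- 1483
  expect_equal(cost_from_records(one,
                                 list(ems_cost_per_transport = 559))$mean_cost,
               1483)
})

test_that("record costing handles empty input and missing tariffs explicitly", {
  empty <- generate_cohort(cohort_spec("hospital", n = 0, seed = 1))
  out <- cost_from_records(empty, list())
  expect_equal(out$n, 0L)
  expect_true(is.na(out$mean_cost))

  coh <- generate_cohort(cohort_spec("hospital", n = 5, seed = 1))
  expect_error(cost_from_records(coh, list()),
               "ems_cost_per_transport")
  pc <- generate_cohort(cohort_spec("primary_care", n = 5, seed = 1))
  expect_error(cost_from_records(pc, list(algorithm_lab_cost = 41,
                                          outpatient_referral_cost = 52)),
               "personnel_cost")
  pc_cost <- cost_from_records(pc, list(algorithm_lab_cost = 41,
                                        personnel_cost = 99,
                                        outpatient_referral_cost = 52))
  expect_equal(pc_cost$mean_cost, 192)
})
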