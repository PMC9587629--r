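test_that("empty and degenerate specs are handled", {
  empty <- generate_cohort(cohort_spec("primary_care", n = 0, seed = 1))
  expect_equal(nrow(empty), 0L)
  expect_true(summarize_cohort(empty)$empty)

  # SD 0 degenerates LOS to a point mass at the mean
  pm <- generate_cohort(cohort_spec("primary_care", n = 10, seed = 1,
                                    los_sd_h = 0))
  expect_equal(unique(pm$los_hours), 3.4)

  expect_error(cohort_spec("primary_care", n = -1), "non-negative")
  expect_error(cohort_spec("primary_care", triage_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  s <- cohort_spec("hospital", n = 500, seed = 9)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_spec("hospital", n = 500, seed = 10))
  expect_false(identical(a$los_hours, c2$los_hours))
})

test_that("cohort record structure respects the setting", {
  pc <- generate_cohort(cohort_spec("primary_care", n = 200, seed = 2))
  expect_true(all(pc$triage %in% c("rule_out", "observation", "rule_in")))
  expect_true(all(is.na(pc$cost_eur)))
  expect_true(all(pc$los_hours >= 0))

  h <- generate_cohort(cohort_spec("hospital", n = 200, seed = 2))
  expect_true(all(h$triage == "not_applicable"))
  expect_true(all(h$admitted))
  expect_true(all(h$cost_eur >= 0))
})

test_that("large-sample marginals match the spec within 3 Monte-Carlo SE", {
  n <- 20000
  pc <- generate_cohort(cohort_spec("primary_care", n = n, seed = 1))
  s <- summarize_cohort(pc)
  expect_lt(abs(s$p_admit - 0.132), 3 * prop_se(0.132, n))
  expect_lt(abs(s$triage_fractions[["rule_out"]] - 1311 / 1711),
            3 * prop_se(1311 / 1711, n))
  expect_lt(abs(s$los_mean_h - 3.4), 3 * 0.740 / sqrt(n))

  h <- generate_cohort(cohort_spec("hospital", n = n, seed = 2))
  sh <- summarize_cohort(h)
  expect_lt(abs(sh$los_mean_h - 22.3), 3 * 22.010 / sqrt(n))
  expect_lt(abs(sh$mean_cost_eur - 1483), 3 * 0.5 * 1483 / sqrt(n))
})

test_that("triage fractions at n = 10000 sit inside the binomial 99% CI", {
  s <- summarize_cohort(generate_cohort(cohort_spec("primary_care",
                                                    n = 10000, seed = 7)))
  z <- qnorm(0.995)
  for (pair in list(c("rule_out", 1311 / 1711), c("observation", 334 / 1711),
                    c("rule_in", 66 / 1711))) {
    p <- as.numeric(pair[2])
    expect_lt(abs(s$triage_fractions[[pair[1]]] - p),
              z * prop_se(p, 10000))
  }
})

test_that("concatenated cohorts summarize to the weighted combination", {
  a <- generate_cohort(cohort_spec("primary_care", n = 300, seed = 4))
  b <- generate_cohort(cohort_spec("primary_care", n = 700, seed = 5))
  both <- rbind(as.data.frame(a), as.data.frame(b))
  class(both) <- c("patient_cohort", "data.frame")
  sa <- summarize_cohort(a); sb <- summarize_cohort(b)
  s <- summarize_cohort(both)
  w <- c(300, 700) / 1000
  expect_equal(s$p_admit, w[1] * sa$p_admit + w[2] * sb$p_admit)
  expect_equal(s$los_mean_h, w[1] * sa$los_mean_h + w[2] * sb$los_mean_h)
  expect_equal(s$event_rate_30d,
               w[1] * sa$event_rate_30d + w[2] * sb$event_rate_30d)
  # pooled SD identity
  pooled_var <- (299 * sa$los_sd_h^2 + 699 * sb$los_sd_h^2 +
                   300 * 700 / 1000 * (sa$los_mean_h - sb$los_mean_h)^2) / 999
  expect_equal(s$los_sd_h, sqrt(pooled_var))
})

test_that("30-day event counts average to the expected 5 per 1485 across seeds", {
  counts <- vapply(1:30, function(seed) {
    coh <- generate_cohort(cohort_spec("primary_care", n = 1485, seed = seed))
    sum(coh$event_30d != "none")
  }, numeric(1))
  expected <- 1485 * 5 / 1485
  se_mean <- sqrt(expected * (1 - 5 / 1485)) / sqrt(30)
  expect_lt(abs(mean(counts) - expected), 3 * se_mean)
})

test_that("single-record summary and CSV round trip are exact", {
  coh <- generate_cohort(cohort_spec("primary_care", n = 1, seed = 3))
  coh$admitted <- TRUE
  expect_equal(summarize_cohort(coh)$p_admit, 1)

  full <- generate_cohort(cohort_spec("hospital", n = 25, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(full, path)
  back <- read_cohort(path)
  expect_equal(back$los_hours, full$los_hours, tolerance = 1e-12)
  expect_equal(back$event_30d, full$event_30d)
  expect_equal(attr(back, "spec")$seed, 8)
})
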