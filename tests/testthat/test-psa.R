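test_that("moment matching parameterizes beta and gamma exactly", {
  d <- troponinCEA:::make_distribution("p", "beta", 0.29, 0.058)
  m <- d$shape1 / (d$shape1 + d$shape2)
  v <- d$shape1 * d$shape2 /
    ((d$shape1 + d$shape2)^2 * (d$shape1 + d$shape2 + 1))
  expect_equal(m, 0.29, tolerance = 1e-12)
  expect_equal(sqrt(v), 0.058, tolerance = 1e-12)

  g <- troponinCEA:::make_distribution("c", "gamma", 559, 111.8)
  expect_equal(g$shape / g$rate, 559, tolerance = 1e-9)
  expect_equal(sqrt(g$shape) / g$rate, 111.8, tolerance = 1e-9)

  expect_error(troponinCEA:::make_distribution("p", "beta", 0, 0.1),
               "infeasible")
  expect_error(troponinCEA:::make_distribution("p", "beta", 0.5, 0.6),
               "infeasible")
})

test_that("fixed distributions are degenerate at the mean", {
  d <- troponinCEA:::make_distribution("x", "fixed", 42, 0)
  s <- troponinCEA:::sample_distribution(d, 10)
  expect_equal(s$values, rep(42, 10))
  # zero SE demotes any family to fixed
  expect_equal(troponinCEA:::make_distribution("x", "gamma", 42, 0)$family,
               "fixed")
})

test_that("samplers recover the specified means within 3 SE", {
  dists <- assign_distributions(default_parameters())
  set.seed(123)
  for (key in c("p_ambulance_to_hospital", "drg_mean", "los_hospital_mean_h")) {
    d <- dists[[key]]
    s <- troponinCEA:::sample_distribution(d, 20000)
    expect_lt(abs(mean(s$values) - d$mean), 3 * d$se / sqrt(20000))
  }
})

test_that("all-fixed distributions collapse the PSA to the deterministic result", {
  p <- default_parameters()
  dists <- assign_distributions(p, uncertainty_policy = list(rel_se = 0))
  expect_true(all(vapply(dists, function(d) d$family == "fixed", logical(1))))
  res <- run_psa(dists, n_draws = 5, seed = 1, params = p)
  det <- troponinCEA:::psa_evaluate(
    vapply(dists, function(d) d$mean, numeric(1)),
    hours_per_year = p$time$hours_per_year
  )
  expect_equal(res$draws$delta_cost, rep(det[["delta_cost"]], 5))
  expect_equal(res$draws$delta_qaly, rep(det[["delta_qaly"]], 5))
  # and the deterministic value sits at the unrounded base-case increment
  expect_equal(det[["delta_cost"]], 192 - 0.9 * 559 - 840664 / 567)
})

test_that("PSA is reproducible for a seed and sensitive to it", {
  dists <- assign_distributions(default_parameters())
  a <- run_psa(dists, 500, seed = 11)
  b <- run_psa(dists, 500, seed = 11)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(dists, 500, seed = 12)
  expect_false(identical(a$draws$delta_cost, c2$draws$delta_cost))
})

test_that("PSA mean increments agree with the deterministic model", {
  dists <- assign_distributions(default_parameters())
  res <- run_psa(dists, 4000, seed = 21)
  se <- sd(res$draws$delta_cost) / sqrt(res$n_draws)
  expect_lt(abs(res$mean_delta_cost - (-1794)), 3 * se)
  seq_ <- sd(res$draws$delta_qaly) / sqrt(res$n_draws)
  expect_lt(abs(res$mean_delta_qaly - 0.0005), 3 * seq_)
})

test_that("CEAC follows its definition and rejects empty input", {
  dists <- assign_distributions(default_parameters())
  res <- run_psa(dists, 1000, seed = 31)
  curve <- ceac(res, c(0, 25600, 76900))
  expect_equal(curve$probability[1], mean(res$draws$delta_cost < 0))
  # dominant strategy: probability near 1 across the Norwegian band
  expect_gt(curve$probability[2], 0.95)
  expect_gt(curve$probability[3], 0.95)
  expect_error(ceac(res, numeric(0)), "non-empty")
})
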