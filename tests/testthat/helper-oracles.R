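# Independent oracles and small utilities shared across the test files.

# Brute-force three-state cohort iteration written as an explicit scalar
# per-year loop, independent of the package's matrix engine.
brute_force_trace <- function(q, q_cvd, incidence, start_state, horizon) {
  non_cvd <- if (start_state == "non_cvd") 1 else 0
  cvd <- if (start_state == "cvd") 1 else 0
  dead <- 0
  occ <- matrix(0, horizon + 1, 3)
  occ[1, ] <- c(non_cvd, cvd, dead)
  for (t in 1:horizon) {
    die_n <- non_cvd * q[t]
    die_c <- cvd * q_cvd[t]
    stay_n <- non_cvd * (1 - q[t]) * (1 - incidence[t])
    new_c <- non_cvd * (1 - q[t]) * incidence[t]
    cvd <- cvd * (1 - q_cvd[t]) + new_c
    non_cvd <- stay_n
    dead <- dead + die_n + die_c
    occ[t + 1, ] <- c(non_cvd, cvd, dead)
  }
  colnames(occ) <- c("non_cvd", "cvd", "dead")
  occ
}

# Monte-Carlo standard error of a proportion
prop_se <- function(p, n) sqrt(p * (1 - p) / n)

# plug-in standard error of a sample SD (delta method on the variance)
sd_se <- function(x) {
  n <- length(x)
  s2 <- stats::var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - s2^2, 0) / n) / (2 * sqrt(s2))
}

default_scenarios <- function() {
  p <- default_parameters()
  list(base = resolve_scenario(p, "base_case"),
       cons = resolve_scenario(p, "conservative"),
       params = p)
}
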