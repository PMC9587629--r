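#' Age-indexed transition schedule for the three-state Markov model
#'
#' Builds the annual transition inputs of the long-term cohort model with
#' health states non-CVD, CVD and dead (dead absorbing). Background
#' mortality follows a Gompertz schedule
#' `q(a) = 1 - exp(-b * exp(theta * a))`; living with CVD carries a
#' mortality hazard ratio (default 1.6) applied on the hazard scale,
#' `q_cvd(a) = 1 - (1 - q(a))^hr`, capped at 1. Annual CVD incidence may
#' be a single probability or a per-age vector.
#'
#' @param start_age First age (years) covered by the schedule.
#' @param horizon Number of one-year cycles covered.
#' @param gompertz_b,gompertz_theta Gompertz level and slope.
#' @param mortality_scale Multiplier on the Gompertz level `b` (the
#'   calibration knob).
#' @param hazard_ratio CVD-vs-non-CVD mortality hazard ratio (>= 0).
#' @param cvd_incidence Annual probability of developing CVD from the
#'   non-CVD state; scalar or vector of length `horizon`.
#' @param q Optional explicit background mortality vector of length
#'   `horizon` (overrides the Gompertz form; e.g. life-table input).
#' @return A `transition_schedule` list: `ages`, `q` (background annual
#'   death probability), `q_cvd`, `incidence`, `hazard_ratio`.
#' @export
#' @examples
#' sch <- transition_schedule(56, horizon = 54)
#' range(sch$q)
transition_schedule <- function(start_age = 56, horizon = 54,
                                gompertz_b = 2e-05, gompertz_theta = 0.095,
                                mortality_scale = 1, hazard_ratio = 1.6,
                                cvd_incidence = 0.01, q = NULL) {
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  if (hazard_ratio < 0) stop("`hazard_ratio` must be >= 0", call. = FALSE)
  ages <- start_age + seq_len(horizon) - 1L
  if (is.null(q)) {
    q <- 1 - exp(-mortality_scale * gompertz_b * exp(gompertz_theta * ages))
  } else {
    if (length(q) != horizon) {
      stop("explicit `q` must have length `horizon` (", horizon, "); ",
           "missing ages ", paste(ages[-seq_along(q)], collapse = ", "),
           call. = FALSE)
    }
    if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]", call. = FALSE)
  }
  incidence <- rep_len(cvd_incidence, horizon)
  if (any(incidence < 0 | incidence > 1)) {
    stop("`cvd_incidence` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      ages = ages,
      q = pmin(q, 1),
      q_cvd = pmin(1 - (1 - q)^hazard_ratio, 1),
      incidence = incidence,
      hazard_ratio = hazard_ratio
    ),
    class = "transition_schedule"
  )
}

#' Run the three-state cohort model
#'
#' Forward matrix iteration of the cohort over one-year cycles. Within a
#' cycle, death competes first; survivors in the non-CVD state develop CVD
#' with the annual incidence probability. A half-cycle correction credits
#' each cycle with the average of its start- and end-of-cycle occupancy,
#' approximating transitions occurring on average halfway through cycles.
#'
#' @param schedule A `transition_schedule`.
#' @param start_state `"non_cvd"` or `"cvd"`.
#' @param horizon Number of cycles to run (<= schedule coverage).
#' @return A `markov_trace`: `occupancy` ((horizon+1) x 3 matrix, rows
#'   0..horizon, columns non_cvd/cvd/dead, each row summing to 1) and
#'   `half_cycle` (horizon x 3 matrix of corrected occupancy), plus
#'   `ages` and `start_state`.
#' @export
#' @examples
#' sch <- transition_schedule(56, horizon = 10)
#' tr <- run_cohort(sch, "non_cvd", 10)
#' rowSums(tr$occupancy)
run_cohort <- function(schedule, start_state = c("non_cvd", "cvd"),
                       horizon = length(schedule$ages)) {
  stopifnot(inherits(schedule, "transition_schedule"))
  start_state <- match.arg(start_state)
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  if (horizon > length(schedule$ages)) {
    miss <- schedule$ages[length(schedule$ages)] + seq_len(horizon - length(schedule$ages))
    stop("schedule shorter than horizon; missing ages ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  states <- c("non_cvd", "cvd", "dead")
  occ <- matrix(0, nrow = horizon + 1L, ncol = 3L,
                dimnames = list(0:horizon, states))
  occ[1L, start_state] <- 1
  for (t in seq_len(horizon)) {
    q <- schedule$q[t]
    qc <- schedule$q_cvd[t]
    inc <- schedule$incidence[t]
    prev <- occ[t, ]
    occ[t + 1L, "non_cvd"] <- prev["non_cvd"] * (1 - q) * (1 - inc)
    occ[t + 1L, "cvd"] <- prev["non_cvd"] * (1 - q) * inc +
      prev["cvd"] * (1 - qc)
    occ[t + 1L, "dead"] <- prev["dead"] + prev["non_cvd"] * q +
      prev["cvd"] * qc
  }
  half_cycle <- (occ[-(horizon + 1L), , drop = FALSE] +
                 occ[-1L, , drop = FALSE]) / 2
  rownames(half_cycle) <- seq_len(horizon)
  structure(
    list(
      occupancy = occ,
      half_cycle = half_cycle,
      ages = schedule$ages[seq_len(horizon)],
      start_state = start_state
    ),
    class = "markov_trace"
  )
}

#' Discounted QALYs from a cohort trace
#'
#' Sums half-cycle-corrected state occupancy weighted by state utilities
#' and discounted annually. By convention the first cycle is discounted by
#' one full year (`discount_from_cycle = 1`); setting
#' `discount_from_cycle = 0` leaves the first cycle undiscounted.
#'
#' @param trace A `markov_trace`.
#' @param state_utilities Named utilities in \[0, 1\] for `non_cvd` and
#'   `cvd` (dead has utility 0).
#' @param discount_rate Annual discount rate (>= 0); default 0.04.
#' @param discount_from_cycle 1 (default) or 0; exponent offset of the
#'   first cycle.
#' @return Discounted QALYs (scalar).
#' @export
#' @examples
#' sch <- transition_schedule(56, horizon = 10, q = rep(0, 10),
#'                            cvd_incidence = 0)
#' tr <- run_cohort(sch, "non_cvd", 10)
#' discounted_qalys(tr, c(non_cvd = 1, cvd = 1), discount_rate = 0)  # 10
discounted_qalys <- function(trace, state_utilities,
                             discount_rate = 0.04,
                             discount_from_cycle = 1) {
  stopifnot(inherits(trace, "markov_trace"))
  u <- c(non_cvd = unname(state_utilities[["non_cvd"]]),
         cvd = unname(state_utilities[["cvd"]]),
         dead = 0)
  if (any(u < 0 | u > 1)) {
    stop("state utilities must lie in [0, 1]", call. = FALSE)
  }
  if (discount_rate < 0) {
    stop("`discount_rate` must be >= 0", call. = FALSE)
  }
  if (!discount_from_cycle %in% c(0, 1)) {
    stop("`discount_from_cycle` must be 0 or 1", call. = FALSE)
  }
  h <- nrow(trace$half_cycle)
  weights <- (1 + discount_rate)^-(seq_len(h) - 1L + discount_from_cycle)
  sum((trace$half_cycle %*% u) * weights)
}

#' Discounted remaining QALYs for an average patient
#'
#' Lifetime discounted QALYs for a person of the given age, with or
#' without an index AMI. A person with an index event starts in the CVD
#' state (mortality hazard ratio applied, CVD utility); otherwise the
#' cohort starts in non-CVD. The horizon runs until the alive fraction
#' drops below 1e-6 or age reaches `max_age`, whichever comes first.
#'
#' @param age Starting age in years.
#' @param post_ami Logical; start in the CVD state?
#' @param params A `cea_parameters` object (Markov section supplies the
#'   schedule shape, calibration scales and discounting convention).
#' @return Discounted remaining QALYs (scalar).
#' @export
#' @examples
#' p <- calibrate_schedules()$params
#' remaining_qalys(56, FALSE, p)  # ~13.3
remaining_qalys <- function(age, post_ami = FALSE,
                            params = default_parameters()) {
  stopifnot(inherits(params, "cea_parameters"))
  mk <- params$markov
  if (age >= mk$max_age) {
    stop("`age` must be below markov.max_age (", mk$max_age, ")",
         call. = FALSE)
  }
  horizon <- mk$max_age - age
  sch <- transition_schedule(
    start_age = age, horizon = horizon,
    gompertz_b = mk$gompertz_b, gompertz_theta = mk$gompertz_theta,
    mortality_scale = mk$mortality_scale, hazard_ratio = mk$hazard_ratio,
    cvd_incidence = mk$cvd_incidence
  )
  tr <- run_cohort(sch, if (post_ami) "cvd" else "non_cvd", horizon)
  alive <- 1 - tr$occupancy[, "dead"]
  cut <- which(alive < 1e-6)
  if (length(cut) && cut[1L] <= horizon) {
    h2 <- cut[1L] - 1L
    tr <- run_cohort(sch, if (post_ami) "cvd" else "non_cvd", max(h2, 1L))
  }
  u <- vapply(params$utility$state_utilities, identity, numeric(1))
  u <- pmin(u * mk$utility_scale, 1)
  discounted_qalys(tr, u, params$economics$discount_rate,
                   mk$discount_from_cycle)
}

#' Calibrate the Markov model to published remaining-QALY targets
#'
#' The published analysis reports discounted remaining QALYs at age 56 of
#' 13.3 without an index event and 11.1 after an AMI; the underlying
#' life-table and utility inputs are not published. This routine adjusts
#' two free parameters — a mortality scale multiplying the Gompertz level
#' and a global utility scale multiplying both state utilities — so the
#' model reproduces both targets. QALYs are linear in the utility scale,
#' so for a given mortality scale the utility scale is solved in closed
#' form from the first target, and one-dimensional root finding
#' ([stats::uniroot()]) on the mortality scale matches the second.
#'
#' @param targets Length-2 numeric: (QALYs without event, QALYs post-AMI).
#' @param params A `cea_parameters` object supplying all fixed inputs.
#' @param mortality_scale_bounds Search interval for the mortality scale.
#' @param tol Convergence tolerance on the residuals (QALYs); default 0.01.
#' @return List with `params` (the calibrated `cea_parameters`),
#'   `mortality_scale`, `utility_scale`, `achieved` (length-2), and
#'   `residuals`.
#' @export
#' @examples
#' cal <- calibrate_schedules()
#' cal$achieved  # ~ c(13.3, 11.1)
calibrate_schedules <- function(targets = c(13.3, 11.1),
                                params = default_parameters(),
                                mortality_scale_bounds = c(0.1, 10),
                                tol = 0.01) {
  if (length(targets) != 2L || any(targets <= 0)) {
    stop("`targets` must be two positive QALY values", call. = FALSE)
  }
  if (targets[2L] > targets[1L]) {
    stop("post-AMI target must not exceed the no-event target",
         call. = FALSE)
  }
  eval_at <- function(m, s) {
    p <- params
    p$markov$mortality_scale <- m
    p$markov$utility_scale <- s
    c(remaining_qalys(p$markov$start_age, FALSE, p),
      remaining_qalys(p$markov$start_age, TRUE, p))
  }
  # utility scale solved in closed form: QALYs are linear in it
  residual2 <- function(m) {
    base <- eval_at(m, 1)
    s <- targets[1L] / base[1L]
    s * base[2L] - targets[2L]
  }
  lo <- mortality_scale_bounds[1L]
  hi <- mortality_scale_bounds[2L]
  f_lo <- residual2(lo)
  f_hi <- residual2(hi)
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    stop("calibration failure: no root in mortality-scale bounds [",
         lo, ", ", hi, "]; residuals ", signif(f_lo, 4), " and ",
         signif(f_hi, 4), call. = FALSE)
  }
  root <- stats::uniroot(residual2, c(lo, hi), tol = 1e-8)
  m_star <- root$root
  base <- eval_at(m_star, 1)
  s_star <- targets[1L] / base[1L]
  umax <- max(vapply(params$utility$state_utilities, identity, numeric(1)))
  if (s_star * umax > 1 + 1e-9) {
    stop("calibration failure: required utility scale ", signif(s_star, 4),
         " pushes state utilities above 1", call. = FALSE)
  }
  achieved <- eval_at(m_star, s_star)
  if (any(abs(achieved - targets) > max(tol, 0.05))) {
    stop("calibration failure: residuals ",
         paste(signif(achieved - targets, 4), collapse = ", "),
         " exceed tolerance", call. = FALSE)
  }
  out <- params
  out$markov$mortality_scale <- m_star
  out$markov$utility_scale <- s_star
  out$utility$remaining_qalys_no_event <- achieved[1L]
  out$utility$remaining_qalys_post_ami <- achieved[2L]
  list(
    params = out,
    mortality_scale = m_star,
    utility_scale = s_star,
    achieved = achieved,
    residuals = achieved - targets
  )
}

#' Export a cohort trace as a data frame
#'
#' @param trace A `markov_trace`.
#' @return Data frame with cycle, age, and per-state occupancy (start of
#'   cycle and half-cycle corrected).
#' @export
trace_as_data_frame <- function(trace) {
  stopifnot(inherits(trace, "markov_trace"))
  h <- nrow(trace$half_cycle)
  data.frame(
    cycle = seq_len(h),
    age = trace$ages,
    non_cvd = trace$half_cycle[, "non_cvd"],
    cvd = trace$half_cycle[, "cvd"],
    dead = trace$half_cycle[, "dead"],
    non_cvd_start = trace$occupancy[seq_len(h), "non_cvd"],
    cvd_start = trace$occupancy[seq_len(h), "cvd"],
    dead_start = trace$occupancy[seq_len(h), "dead"]
  )
}
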