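#' Expected ambulance transport cost
#'
#' Expected emergency-medical-services cost per patient: probability of an
#' ambulance transport times the unit cost per transport (EUR 559 in 2020).
#'
#' @param p Probability of transport, in \[0, 1\].
#' @param unit_cost Cost per transport in EUR (non-negative).
#' @return Expected cost in EUR (unrounded; whole-EUR rounding is applied
#'   at the reporting boundary).
#' @export
#' @examples
#' round(expected_ambulance_cost(0.29, 559))  # 162
#' round(expected_ambulance_cost(0.90, 559))  # 503
expected_ambulance_cost <- function(p, unit_cost) {
  if (!is.numeric(p) || any(p < 0 | p > 1)) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(unit_cost) || any(unit_cost < 0)) {
    stop("`unit_cost` must be non-negative", call. = FALSE)
  }
  p * unit_cost
}

#' Additional primary-care cost of the 0/1-h algorithm
#'
#' Per-patient add-on cost of running the troponin algorithm at the
#' emergency primary care clinic: laboratory and additional diagnostics
#' (EUR 41), personnel time (EUR 99 by wages in the base case, EUR 137 by
#' tariffs in the conservative scenario), and referrals to outpatient
#' cardiac testing (EUR 52).
#'
#' @param scenario A resolved `cea_scenario`.
#' @return List with `total` (EUR) and a named `breakdown` vector
#'   (`diagnostics`, `personnel`, `outpatient_referral`).
#' @export
#' @examples
#' sc <- resolve_scenario(default_parameters(), "base_case")
#' primary_addon_cost(sc)$total  # 192
primary_addon_cost <- function(scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  co <- scenario$params$cost
  breakdown <- c(
    diagnostics = co$algorithm_lab_cost,
    personnel = scenario$personnel_cost,
    outpatient_referral = co$outpatient_referral_cost
  )
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Mean DRG cost per admitted low-risk patient
#'
#' Total DRG-based hospital expenditure for the low-risk cohort divided by
#' the cohort size, rounded to whole EUR (the reporting convention).
#'
#' @param total Total DRG expenditure in EUR.
#' @param n Cohort size (> 0).
#' @return Mean per-patient cost in EUR, whole-EUR rounded.
#' @export
#' @examples
#' drg_mean_cost(840664, 567)  # 1483
drg_mean_cost <- function(total, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(total) || total < 0) {
    stop("`total` must be non-negative", call. = FALSE)
  }
  round(total / n)
}

#' Expected per-patient strategy cost (decision tree, top-down)
#'
#' Builds the per-patient expected cost of one management strategy under a
#' resolved scenario. Both arms share the initial EMS transport to primary
#' care and the primary-care consultation (assumed similar in the two
#' settings, so they cancel in the incremental comparison). The
#' primary-care arm adds the 0/1-h algorithm add-on; the hospital arm adds
#' the ambulance transfer to hospital and the mean DRG cost. Each
#' component is rounded to whole EUR before summation, matching the
#' reporting convention in which printed totals equal sums of printed
#' components.
#'
#' @param scenario A resolved `cea_scenario`.
#' @param strategy `"primary_care_algorithm"` or `"hospital_standard"`.
#' @return A `strategy_cost` object: `components` data frame (label,
#'   unit_cost, probability, expected whole-EUR cost), `total` (EUR),
#'   `strategy`, `scenario`.
#' @export
#' @examples
#' sc <- resolve_scenario(default_parameters(), "base_case")
#' strategy_total_cost(sc, "primary_care_algorithm")$total  # 520
#' strategy_total_cost(sc, "hospital_standard")$total       # 2314
strategy_total_cost <- function(scenario,
                                strategy = c("primary_care_algorithm",
                                             "hospital_standard")) {
  stopifnot(inherits(scenario, "cea_scenario"))
  strategy <- match.arg(strategy)
  co <- scenario$params$cost

  shared <- data.frame(
    label = c("ems_to_primary", "consultation"),
    unit_cost = c(co$ems_cost_per_transport, co$consultation_cost),
    probability = c(co$p_ambulance_to_primary, 1),
    stringsAsFactors = FALSE
  )
  if (strategy == "primary_care_algorithm") {
    addon <- primary_addon_cost(scenario)
    own <- data.frame(
      label = "algorithm_addon",
      unit_cost = addon$total,
      probability = 1,
      stringsAsFactors = FALSE
    )
  } else {
    own <- data.frame(
      label = c("ems_to_hospital", "hospital_drg"),
      unit_cost = c(co$ems_cost_per_transport,
                    drg_mean_cost(co$drg_total, co$n_hospital_cohort)),
      probability = c(scenario$p_ambulance_to_hospital, 1),
      stringsAsFactors = FALSE
    )
  }
  components <- rbind(shared, own)
  components$expected <- round(
    expected_ambulance_cost(components$probability, components$unit_cost)
  )
  out <- list(
    strategy = strategy,
    scenario = scenario$name,
    components = components,
    total = sum(components$expected)
  )
  class(out) <- "strategy_cost"
  out
}

#' @export
print.strategy_cost <- function(x, ...) {
  cat("<strategy_cost> ", x$strategy, " / ", x$scenario, "\n", sep = "")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-18s EUR %5d  (unit %s; p = %s)\n",
                x$components$label[i], x$components$expected[i],
                format(x$components$unit_cost[i]),
                format(x$components$probability[i])))
  }
  cat("  TOTAL              EUR", x$total, "\n")
  invisible(x)
}

#' Bottom-up mean cost from patient-level records
#'
#' Empirical per-patient mean cost computed from a cohort of patient
#' records, with component attribution. For hospital records the
#' per-record cost is the individual DRG-based cost plus the ambulance
#' transport cost when one was used; for primary-care records it is the
#' 0/1-h algorithm add-on (diagnostics + personnel + outpatient referral).
#' Shared components (initial EMS, consultation) are not attributed here;
#' they cancel in the incremental comparison. On large synthetic cohorts
#' the result converges to the non-shared part of the analytic decision
#' tree.
#'
#' @param records A `patient_cohort` data frame from [generate_cohort()]
#'   (or equivalent), all from one setting.
#' @param tariffs Named list of unit costs; must contain
#'   `ems_cost_per_transport` and, for primary-care records,
#'   `algorithm_lab_cost`, `personnel_cost`, `outpatient_referral_cost`.
#' @return List with `n`, `mean_cost`, `se`, and `components` (named mean
#'   contributions). Empty input returns the sentinel
#'   `list(n = 0, mean_cost = NA_real_, se = NA_real_, components = NULL)`.
#' @export
cost_from_records <- function(records, tariffs) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(n = 0L, mean_cost = NA_real_, se = NA_real_,
                components = NULL))
  }
  setting <- unique(records$setting)
  if (length(setting) != 1L) {
    stop("`records` must come from a single setting", call. = FALSE)
  }
  need <- function(key) {
    if (is.null(tariffs[[key]])) {
      stop("tariff map is missing key: ", key, call. = FALSE)
    }
    tariffs[[key]]
  }
  if (setting == "hospital") {
    ems <- need("ems_cost_per_transport")
    per_record <- records$cost_eur + records$ambulance * ems
    components <- c(
      hospital_drg = mean(records$cost_eur),
      ems_to_hospital = mean(records$ambulance * ems)
    )
  } else {
    addon <- c(
      diagnostics = need("algorithm_lab_cost"),
      personnel = need("personnel_cost"),
      outpatient_referral = need("outpatient_referral_cost")
    )
    per_record <- rep(sum(addon), nrow(records))
    components <- addon
  }
  list(
    n = nrow(records),
    mean_cost = mean(per_record),
    se = stats::sd(per_record) / sqrt(nrow(records)),
    components = components
  )
}
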