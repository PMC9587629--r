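#' Per-strategy outcome bundle
#'
#' Convenience constructor combining expected cost, QALY loss and mean
#' length of stay for one strategy under one scenario.
#'
#' @param scenario A resolved `cea_scenario`.
#' @param strategy `"primary_care_algorithm"` or `"hospital_standard"`.
#' @return A `strategy_outcome` list: `cost` ([strategy_total_cost()]
#'   result), `qaly` ([strategy_qaly()] result), `mean_los_h`, `strategy`,
#'   `scenario`.
#' @export
strategy_outcome <- function(scenario,
                             strategy = c("primary_care_algorithm",
                                          "hospital_standard")) {
  stopifnot(inherits(scenario, "cea_scenario"))
  strategy <- match.arg(strategy)
  setting <- if (strategy == "primary_care_algorithm") "primary_care"
             else "hospital"
  out <- list(
    strategy = strategy,
    scenario = scenario$name,
    cost = strategy_total_cost(scenario, strategy),
    qaly = strategy_qaly(scenario, setting),
    mean_los_h = if (setting == "primary_care") scenario$los_primary_mean_h
                 else scenario$params$time$los_hospital_mean_h
  )
  class(out) <- "strategy_outcome"
  out
}

#' Incremental cost and QALY difference
#'
#' Differences are taken as intervention minus comparator
#' (primary care minus hospital). Costs are differenced on the rendered
#' whole-EUR totals (sums of rounded components, the reporting
#' convention); QALYs are differenced on the unrounded per-arm losses, so
#' a positive QALY difference is a health gain for the primary-care arm.
#'
#' @param primary_outcome,comparator_outcome `strategy_outcome` objects
#'   under the same scenario.
#' @return List with `delta_cost` (EUR), `delta_qaly` (QALYs),
#'   `delta_los_h` (hours), and `scenario`.
#' @export
#' @examples
#' sc <- resolve_scenario(default_parameters(), "base_case")
#' inc <- incremental(strategy_outcome(sc, "primary_care_algorithm"),
#'                    strategy_outcome(sc, "hospital_standard"))
#' inc$delta_cost   # -1794
#' round(inc$delta_qaly, 4)  # 0.0005
incremental <- function(primary_outcome, comparator_outcome) {
  stopifnot(inherits(primary_outcome, "strategy_outcome"),
            inherits(comparator_outcome, "strategy_outcome"))
  if (!identical(primary_outcome$scenario, comparator_outcome$scenario)) {
    stop("outcomes come from different scenarios: ",
         primary_outcome$scenario, " vs ", comparator_outcome$scenario,
         call. = FALSE)
  }
  list(
    scenario = primary_outcome$scenario,
    delta_cost = primary_outcome$cost$total - comparator_outcome$cost$total,
    delta_qaly = primary_outcome$qaly$total - comparator_outcome$qaly$total,
    delta_los_h = primary_outcome$mean_los_h - comparator_outcome$mean_los_h
  )
}

#' ICER with cost-effectiveness plane quadrant semantics
#'
#' Classifies the incremental pair on the cost-effectiveness plane and
#' computes the incremental cost-effectiveness ratio where one is
#' defined. A strategy that is cheaper and more effective is dominant and
#' carries no ratio; costlier and less effective is dominated. In the
#' trade-off quadrants (NE: costlier and more effective; SW: cheaper and
#' less effective) the ratio is `delta_cost / delta_qaly`. A zero QALY
#' difference with a non-zero cost difference is classified as a
#' cost-only comparison rather than divided.
#'
#' @param delta_cost Incremental cost (EUR, intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @return An `icer_result` list: `delta_cost`, `delta_qaly`, `quadrant`
#'   (`dominant`, `dominated`, `ne_trade`, `sw_trade`, `cost_only`,
#'   `effect_only`, or `indifferent`), and `icer` (EUR/QALY, `NA` outside
#'   the trade quadrants).
#' @export
#' @examples
#' icer(-1672, -0.0019)$icer      # 880000 (SW trade-off)
#' icer(-1794, 0.0005)$quadrant   # "dominant"
icer <- function(delta_cost, delta_qaly) {
  if (!is.finite(delta_cost) || !is.finite(delta_qaly)) {
    stop("`delta_cost` and `delta_qaly` must be finite", call. = FALSE)
  }
  quadrant <- if (delta_qaly == 0) {
    if (delta_cost == 0) "indifferent" else "cost_only"
  } else if (delta_cost == 0) {
    "effect_only"
  } else if (delta_cost < 0 && delta_qaly > 0) {
    "dominant"
  } else if (delta_cost > 0 && delta_qaly < 0) {
    "dominated"
  } else if (delta_cost > 0 && delta_qaly > 0) {
    "ne_trade"
  } else {
    "sw_trade"
  }
  ratio <- if (quadrant %in% c("ne_trade", "sw_trade")) {
    delta_cost / delta_qaly
  } else {
    NA_real_
  }
  structure(
    list(delta_cost = delta_cost, delta_qaly = delta_qaly,
         quadrant = quadrant, icer = ratio),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result> quadrant: ", x$quadrant, "\n",
      "  delta cost: EUR ", format(x$delta_cost),
      ";  delta QALY: ", format(x$delta_qaly), "\n", sep = "")
  if (is.finite(x$icer)) {
    cat("  ICER: EUR ", format(round(x$icer)), " per QALY\n", sep = "")
  }
  invisible(x)
}

#' Cost-effectiveness verdict against a threshold band
#'
#' Applies the standard decision rule at both ends of the
#' willingness-to-pay band (Norwegian convention 25,600--76,900 EUR/QALY).
#' A dominant strategy is always cost-effective and a dominated one never.
#' In the NE quadrant the strategy is cost-effective when the ICER is at
#' or below the threshold; in the SW quadrant when the savings per QALY
#' lost are at or above the threshold (the willingness-to-accept rule).
#' Boundary equality counts as cost-effective.
#'
#' @param result An `icer_result`.
#' @param threshold_band Length-2 numeric `(low, high)` in EUR/QALY.
#' @return List with `at_low` and `at_high` (each `"cost_effective"`,
#'   `"not_cost_effective"`, or `"dominant"`), and the band.
#' @export
#' @examples
#' verdict(icer(-1672, -0.0019), c(25600, 76900))
verdict <- function(result, threshold_band = c(25600, 76900)) {
  stopifnot(inherits(result, "icer_result"))
  if (length(threshold_band) != 2L || any(threshold_band < 0) ||
      threshold_band[1L] > threshold_band[2L]) {
    stop("`threshold_band` must be non-negative (low, high)", call. = FALSE)
  }
  one <- function(lambda) {
    switch(result$quadrant,
      dominant = "dominant",
      dominated = "not_cost_effective",
      cost_only = if (result$delta_cost < 0) "cost_effective"
                  else "not_cost_effective",
      effect_only = if (result$delta_qaly > 0) "cost_effective"
                    else "not_cost_effective",
      indifferent = "cost_effective",
      ne_trade = if (result$icer <= lambda) "cost_effective"
                 else "not_cost_effective",
      sw_trade = if (result$icer >= lambda) "cost_effective"
                 else "not_cost_effective"
    )
  }
  list(
    at_low = one(threshold_band[1L]),
    at_high = one(threshold_band[2L]),
    threshold_band = threshold_band
  )
}

#' Net monetary benefit
#'
#' `lambda * delta_qaly - delta_cost` at willingness-to-pay `lambda`;
#' positive values favour the intervention.
#'
#' @param delta_cost Incremental cost (EUR).
#' @param delta_qaly Incremental QALYs.
#' @param lambda Willingness-to-pay (EUR/QALY, >= 0).
#' @return Net monetary benefit in EUR.
#' @export
#' @examples
#' net_monetary_benefit(-1794, 0.0005, 25600)  # 1806.8
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  lambda * delta_qaly - delta_cost
}
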