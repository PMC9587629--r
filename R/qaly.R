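#' QALY loss from waiting (length of stay)
#'
#' Health lost while waiting for rule-out: the fraction of a year spent in
#' assessment multiplied by the utility decrement experienced while
#' waiting. Returned as a (non-positive) QALY amount.
#'
#' @param los_hours Length of stay in hours (non-negative).
#' @param decrement Utility decrement per year of waiting, in \[0, 1\].
#' @param hours_per_year Hours per year; default 8766 (365.25 x 24).
#' @return QALY loss (<= 0), unrounded.
#' @export
#' @examples
#' round(los_qaly_loss(22.3, 0.232), 5)  # -0.00059
#' round(los_qaly_loss(3.4, 0.232), 5)   # -0.00009
los_qaly_loss <- function(los_hours, decrement, hours_per_year = 8766) {
  if (!is.numeric(los_hours) || any(los_hours < 0)) {
    stop("`los_hours` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(decrement) || any(decrement < 0 | decrement > 1)) {
    stop("`decrement` must be in [0, 1]", call. = FALSE)
  }
  if (hours_per_year <= 0) {
    stop("`hours_per_year` must be positive", call. = FALSE)
  }
  -(los_hours / hours_per_year) * decrement
}

#' QALY loss from excess 30-day events
#'
#' Expected lifetime QALYs lost through the 30-day AMI/death rate among
#' patients not admitted: event probability times the discounted lifetime
#' QALY difference between an average 56-year-old with and without an
#' index event (default 2.222, printed rounded as 13.3 - 11.1).
#'
#' @param event_rate 30-day event probability, in \[0, 1\].
#' @param qaly_loss_per_event Discounted QALYs lost per event (>= 0).
#' @return QALY loss (<= 0), unrounded.
#' @export
#' @examples
#' round(event_qaly_loss(5 / 1485, 2.222), 5)  # -0.00748
event_qaly_loss <- function(event_rate, qaly_loss_per_event) {
  if (!is.numeric(event_rate) || any(event_rate < 0 | event_rate > 1)) {
    stop("`event_rate` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(qaly_loss_per_event) || any(qaly_loss_per_event < 0)) {
    stop("`qaly_loss_per_event` must be non-negative", call. = FALSE)
  }
  -event_rate * qaly_loss_per_event
}

#' Per-strategy QALY loss under a scenario
#'
#' Combines the waiting-time component and the excess-event component for
#' one care setting. In the base case the 30-day event rates in both
#' low-risk cohorts lie below the accepted miss rate, so event-related
#' health loss is set to zero in both arms; the conservative scenario
#' applies each arm's observed 30-day rate.
#'
#' @param scenario A resolved `cea_scenario`.
#' @param setting `"primary_care"` or `"hospital"`.
#' @return A `qaly_loss` list: `los_component`, `event_component`, `total`
#'   (all QALYs, <= 0, unrounded), plus `setting` and `scenario`.
#' @export
#' @examples
#' sc <- resolve_scenario(default_parameters(), "base_case")
#' round(strategy_qaly(sc, "hospital")$total, 5)  # -0.00059
strategy_qaly <- function(scenario, setting = c("primary_care", "hospital")) {
  stopifnot(inherits(scenario, "cea_scenario"))
  setting <- match.arg(setting)
  p <- scenario$params
  los_h <- if (setting == "primary_care") scenario$los_primary_mean_h
           else p$time$los_hospital_mean_h
  los_component <- los_qaly_loss(
    los_h, p$utility$waiting_utility_decrement, p$time$hours_per_year
  )
  event_component <- if (scenario$include_excess_events) {
    rate <- if (setting == "primary_care") p$events$rate_primary_30d
            else p$events$rate_hospital_30d
    event_qaly_loss(rate, p$utility$qaly_loss_per_event)
  } else {
    0
  }
  out <- list(
    setting = setting,
    scenario = scenario$name,
    los_component = los_component,
    event_component = event_component,
    total = los_component + event_component
  )
  class(out) <- "qaly_loss"
  out
}

#' @export
print.qaly_loss <- function(x, ...) {
  cat("<qaly_loss> ", x$setting, " / ", x$scenario, "\n",
      sprintf("  LOS:   %.5f\n  AMI:   %.5f\n  total: %.5f\n",
              x$los_component, x$event_component, x$total), sep = "")
  invisible(x)
}
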