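#' Default model parameters
#'
#' Returns the full parameter set of the cost-effectiveness model with its
#' published default values: 2020 Norwegian unit costs and micro-costing
#' conversion rules, length-of-stay moments for the two care settings,
#' utility inputs, 30-day event rates, and economic settings (discount rate
#' and the Norwegian willingness-to-pay band).
#'
#' Parameters are grouped in sections:
#' \describe{
#'   \item{cost}{Unit costs in 2020 EUR and costing conversion constants.
#'     `ems_cost_per_transport` (559), `p_ambulance_to_primary` (0.29),
#'     `p_ambulance_to_hospital_base` (0.90) and `_conservative` (0.75),
#'     `consultation_cost` (166), `algorithm_lab_cost` (41),
#'     `personnel_cost_wage` (99), `personnel_cost_tariff` (137),
#'     `outpatient_referral_cost` (52), `drg_total` (840664) with
#'     `n_hospital_cohort` (567), `nok_per_eur` (10.73),
#'     `payroll_multiplier` (1.3), `helfo_multiplier` (2.0).}
#'   \item{time}{Length-of-stay moments in hours: primary care 3.4 (SD 0.740)
#'     base case, 4.0 (SD 0.870) conservative; hospital 22.3 (SD 22.010);
#'     `hours_per_year` (8766 = 365.25 x 24).}
#'   \item{utility}{`waiting_utility_decrement` (0.232 utility units per
#'     year of waiting), `qaly_loss_per_event` (2.222, the discounted
#'     lifetime QALY difference between an average 56-year-old with and
#'     without an index AMI, printed rounded as 13.3 - 11.1),
#'     `remaining_qalys_no_event` (13.3), `remaining_qalys_post_ami` (11.1),
#'     and per-state `state_utilities` for the Markov model.}
#'   \item{events}{30-day AMI/death rates: primary care 5/1485, hospital
#'     2/862, conservative excess rate 0.001, and the base-case flag that
#'     zeroes event-related health loss in both arms.}
#'   \item{economics}{`discount_rate` (0.04 per year), willingness-to-pay
#'     band 25600--76900 EUR/QALY, `reference_year` (2020).}
#'   \item{markov}{Gompertz background-mortality shape (`gompertz_b`,
#'     `gompertz_theta`), `start_age` (56), CVD mortality `hazard_ratio`
#'     (1.6), annual `cvd_incidence`, `max_age` (110), calibration scales
#'     and the cycle-1 discounting convention.}
#' }
#'
#' `induced_testing_fraction` (0.15, plausible range 0.10--0.15) is stored
#' for sensitivity use only; base outputs exclude it because those patients
#' are already part of the primary-care cohort the costs are estimated on.
#'
#' @return A named list of parameter sections, class `cea_parameters`, with
#'   a `provenance` attribute mapping each leaf field to `"default"`.
#' @seealso [load_parameters()], [resolve_scenario()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$cost$ems_cost_per_transport
default_parameters <- function() {
  params <- list(
    cost = list(
      ems_cost_per_transport = 559,
      p_ambulance_to_primary = 0.29,
      p_ambulance_to_hospital_base = 0.90,
      p_ambulance_to_hospital_conservative = 0.75,
      consultation_cost = 166,
      algorithm_lab_cost = 41,
      personnel_cost_wage = 99,
      personnel_cost_tariff = 137,
      outpatient_referral_cost = 52,
      drg_total = 840664,
      n_hospital_cohort = 567,
      nok_per_eur = 10.73,
      payroll_multiplier = 1.3,
      helfo_multiplier = 2.0
    ),
    time = list(
      los_primary_base_mean_h = 3.4,
      los_primary_base_sd_h = 0.740,
      los_primary_conservative_mean_h = 4.0,
      los_primary_conservative_sd_h = 0.870,
      los_hospital_mean_h = 22.3,
      los_hospital_sd_h = 22.010,
      hours_per_year = 8766
    ),
    utility = list(
      waiting_utility_decrement = 0.232,
      qaly_loss_per_event = 2.222,
      remaining_qalys_no_event = 13.3,
      remaining_qalys_post_ami = 11.1,
      state_utilities = list(non_cvd = 0.87, cvd = 0.80)
    ),
    events = list(
      rate_primary_30d = 5 / 1485,
      rate_hospital_30d = 2 / 862,
      excess_rate_conservative = 0.001,
      base_case_event_loss_zero = TRUE
    ),
    economics = list(
      discount_rate = 0.04,
      threshold_low = 25600,
      threshold_high = 76900,
      reference_year = 2020
    ),
    markov = list(
      start_age = 56,
      gompertz_b = 2e-05,
      gompertz_theta = 0.095,
      hazard_ratio = 1.6,
      cvd_incidence = 0.01,
      max_age = 110,
      mortality_scale = 1,
      utility_scale = 1,
      discount_from_cycle = 1
    ),
    induced_testing_fraction = 0.15
  )
  leaves <- param_leaves(params)
  attr(params, "provenance") <- stats::setNames(
    rep("default", length(leaves)), leaves
  )
  class(params) <- "cea_parameters"
  params
}

# flat "section.field" keys for every scalar leaf (state_utilities and the
# like descend one extra level)
param_leaves <- function(x, prefix = character()) {
  if (!is.list(x)) {
    return(paste(prefix, collapse = "."))
  }
  unlist(lapply(names(x), function(nm) {
    param_leaves(x[[nm]], c(prefix, nm))
  }), use.names = FALSE)
}

#' Load and validate model parameters
#'
#' Builds the full validated parameter set from an optional configuration
#' source, filling every unspecified field with its published default.
#' Unknown keys are rejected rather than silently ignored, and each leaf
#' field carries a provenance label (`"default"` or `"user"`).
#'
#' @param config Either `NULL` (all defaults), a path to a YAML file, or a
#'   nested named list with the same section/field structure as
#'   [default_parameters()]. Only supplied fields are overridden.
#' @return A validated `cea_parameters` object.
#' @export
#' @examples
#' p <- load_parameters(list(economics = list(discount_rate = 0)))
#' p$economics$discount_rate
#' attr(p, "provenance")[["economics.discount_rate"]]
load_parameters <- function(config = NULL) {
  params <- default_parameters()
  if (is.null(config)) {
    validate_parameters(params)
    return(params)
  }
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("`config` must be NULL, a file path, or a named list", call. = FALSE)
  }
  prov <- attr(params, "provenance")
  merged <- merge_params(unclass(params), config, prefix = character())
  params <- merged$value
  prov[merged$touched] <- "user"
  attr(params, "provenance") <- prov
  class(params) <- "cea_parameters"
  validate_parameters(params)
  params
}

merge_params <- function(base, override, prefix) {
  if (is.null(names(override)) || any(names(override) == "")) {
    stop("configuration entries must be named (at ",
         if (length(prefix)) paste(prefix, collapse = ".") else "top level",
         ")", call. = FALSE)
  }
  touched <- character()
  for (nm in names(override)) {
    key <- paste(c(prefix, nm), collapse = ".")
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    if (is.list(base[[nm]])) {
      if (!is.list(override[[nm]])) {
        stop("configuration key ", key, " must be a section, not a scalar",
             call. = FALSE)
      }
      sub <- merge_params(base[[nm]], override[[nm]], c(prefix, nm))
      base[[nm]] <- sub$value
      touched <- c(touched, sub$touched)
    } else {
      val <- override[[nm]]
      if (!(is.numeric(val) || is.logical(val)) || length(val) != 1L ||
          is.na(val)) {
        stop("configuration key ", key,
             " must be a single non-missing numeric or logical value",
             call. = FALSE)
      }
      base[[nm]] <- val
      touched <- c(touched, key)
    }
  }
  list(value = base, touched = touched)
}

validate_parameters <- function(params) {
  co <- params$cost
  check_prob <- function(x, name) {
    if (!is.numeric(x) || x < 0 || x > 1) {
      stop("parameter ", name, " must be a probability in [0, 1], got ",
           format(x), call. = FALSE)
    }
  }
  check_nonneg <- function(x, name) {
    if (!is.numeric(x) || x < 0) {
      stop("parameter ", name, " must be non-negative, got ", format(x),
           call. = FALSE)
    }
  }
  for (nm in c("ems_cost_per_transport", "consultation_cost",
               "algorithm_lab_cost", "personnel_cost_wage",
               "personnel_cost_tariff", "outpatient_referral_cost",
               "drg_total")) {
    check_nonneg(co[[nm]], paste0("cost.", nm))
  }
  for (nm in c("p_ambulance_to_primary", "p_ambulance_to_hospital_base",
               "p_ambulance_to_hospital_conservative")) {
    check_prob(co[[nm]], paste0("cost.", nm))
  }
  if (co$n_hospital_cohort <= 0) {
    stop("parameter cost.n_hospital_cohort must be > 0", call. = FALSE)
  }
  ti <- params$time
  for (nm in c("los_primary_base_mean_h", "los_primary_conservative_mean_h",
               "los_hospital_mean_h", "hours_per_year")) {
    if (ti[[nm]] <= 0) {
      stop("parameter time.", nm, " must be > 0", call. = FALSE)
    }
  }
  for (nm in c("los_primary_base_sd_h", "los_primary_conservative_sd_h",
               "los_hospital_sd_h")) {
    check_nonneg(ti[[nm]], paste0("time.", nm))
  }
  ut <- params$utility
  check_prob(ut$waiting_utility_decrement, "utility.waiting_utility_decrement")
  check_nonneg(ut$qaly_loss_per_event, "utility.qaly_loss_per_event")
  for (nm in names(ut$state_utilities)) {
    check_prob(ut$state_utilities[[nm]],
               paste0("utility.state_utilities.", nm))
  }
  ev <- params$events
  for (nm in c("rate_primary_30d", "rate_hospital_30d",
               "excess_rate_conservative")) {
    check_prob(ev[[nm]], paste0("events.", nm))
  }
  ec <- params$economics
  check_nonneg(ec$discount_rate, "economics.discount_rate")
  if (ec$threshold_low > ec$threshold_high) {
    stop("economics.threshold_low must not exceed economics.threshold_high",
         call. = FALSE)
  }
  mk <- params$markov
  check_nonneg(mk$hazard_ratio, "markov.hazard_ratio")
  check_prob(mk$cvd_incidence, "markov.cvd_incidence")
  if (mk$max_age <= mk$start_age) {
    stop("markov.max_age must exceed markov.start_age", call. = FALSE)
  }
  itf <- params$induced_testing_fraction
  check_prob(itf, "induced_testing_fraction")
  invisible(params)
}

#' @export
print.cea_parameters <- function(x, ...) {
  prov <- attr(x, "provenance")
  n_user <- sum(prov == "user")
  cat("<cea_parameters> ", length(prov), " fields (",
      n_user, " user-overridden)\n", sep = "")
  for (sec in names(x)) {
    if (is.list(x[[sec]])) {
      cat("  $", sec, ": ", length(param_leaves(x[[sec]])), " fields\n",
          sep = "")
    } else {
      cat("  $", sec, " = ", format(x[[sec]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Resolve a named analysis scenario
#'
#' Fixes the four scenario-varied inputs of the model. The base case takes
#' the most-likely values; the conservative scenario takes the worst-case
#' values for managing low-risk patients in primary care: personnel time
#' costed by tariffs instead of wages, inclusion of excess 30-day events,
#' a lower ambulance-transport probability for admissions from primary
#' care, and the upper range of the primary-care length of stay.
#'
#' @param params A `cea_parameters` object.
#' @param name `"base_case"` or `"conservative"`.
#' @return A `cea_scenario` list with the resolved values
#'   (`personnel_cost`, `personnel_costing`, `include_excess_events`,
#'   `p_ambulance_to_hospital`, `los_primary_mean_h`, `los_primary_sd_h`)
#'   and the full parameter set in `$params`.
#' @export
#' @examples
#' sc <- resolve_scenario(default_parameters(), "base_case")
#' sc$personnel_cost        # 99 (wages)
#' sc$p_ambulance_to_hospital
resolve_scenario <- function(params = default_parameters(),
                             name = c("base_case", "conservative")) {
  if (!inherits(params, "cea_parameters")) {
    stop("`params` must be a cea_parameters object", call. = FALSE)
  }
  valid <- c("base_case", "conservative")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("unknown scenario ", deparse(substitute(name)), ": valid names are ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  base <- identical(name, "base_case")
  sc <- list(
    name = name,
    personnel_costing = if (base) "wage" else "tariff",
    personnel_cost = if (base) params$cost$personnel_cost_wage
                     else params$cost$personnel_cost_tariff,
    include_excess_events = !base,
    p_ambulance_to_hospital = if (base)
      params$cost$p_ambulance_to_hospital_base
    else params$cost$p_ambulance_to_hospital_conservative,
    los_primary_mean_h = if (base) params$time$los_primary_base_mean_h
                         else params$time$los_primary_conservative_mean_h,
    los_primary_sd_h = if (base) params$time$los_primary_base_sd_h
                       else params$time$los_primary_conservative_sd_h,
    params = params
  )
  class(sc) <- "cea_scenario"
  sc
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat("<cea_scenario> ", x$name, "\n",
      "  personnel: EUR ", x$personnel_cost, " (", x$personnel_costing, ")\n",
      "  P(ambulance to hospital): ", x$p_ambulance_to_hospital, "\n",
      "  primary-care LOS: ", x$los_primary_mean_h, " h (SD ",
      x$los_primary_sd_h, ")\n",
      "  excess 30-day events: ",
      if (x$include_excess_events) "included" else "excluded", "\n", sep = "")
  invisible(x)
}

#' Apply a micro-costing gross-up rule
#'
#' Converts a raw pay or reimbursement amount into a full economic cost:
#' the `payroll` rule multiplies average pay by 1.3 to include payroll
#' taxes and social charges; the `helfo` rule doubles HELFO reimbursements
#' to cover other financing sources.
#'
#' @param amount Non-negative amount in EUR.
#' @param rule `"payroll"` or `"helfo"`.
#' @param params Parameter set supplying the multipliers.
#' @return The grossed-up amount in EUR.
#' @export
#' @examples
#' gross_up(100, "payroll")  # 130
#' gross_up(50, "helfo")     # 100
gross_up <- function(amount, rule = c("payroll", "helfo"),
                     params = default_parameters()) {
  rule <- match.arg(rule)
  if (!is.numeric(amount) || any(amount < 0)) {
    stop("`amount` must be non-negative", call. = FALSE)
  }
  mult <- switch(rule,
    payroll = params$cost$payroll_multiplier,
    helfo = params$cost$helfo_multiplier
  )
  amount * mult
}

#' Convert NOK to 2020 EUR
#'
#' Fixed 2020 exchange rate: EUR 1.00 = NOK 10.73.
#'
#' @param amount_nok Amount in NOK (finite).
#' @param nok_per_eur Exchange rate; default 10.73.
#' @return Amount in EUR.
#' @export
#' @examples
#' convert_currency(10.73)  # 1
convert_currency <- function(amount_nok, nok_per_eur = 10.73) {
  if (!is.numeric(amount_nok) || any(!is.finite(amount_nok))) {
    stop("`amount_nok` must be finite", call. = FALSE)
  }
  if (!is.numeric(nok_per_eur) || nok_per_eur <= 0) {
    stop("`nok_per_eur` must be positive", call. = FALSE)
  }
  amount_nok / nok_per_eur
}
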