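#' Run the full cost-effectiveness pipeline
#'
#' Orchestrates the deterministic model end to end for the requested
#' scenarios: per-arm expected costs, QALY losses and LOS, incremental
#' results with quadrant classification and threshold verdicts, and
#' optionally the probabilistic sensitivity analysis and the national
#' budget-impact projection. Deterministic stages do not depend on the
#' seed; the seed governs the PSA (and any cohort generation done by the
#' caller).
#'
#' @param params A `cea_parameters` object (or `NULL` for defaults).
#' @param scenarios Character vector of scenario names.
#' @param seed Integer seed for stochastic stages.
#' @param psa_draws Number of PSA draws (0 disables the PSA stage).
#' @param budget Logical; include the budget-impact stage (coverage at
#'   `budget_distance_km`)?
#' @param budget_distance_km Distance tier used by the budget stage.
#' @return A `cea_bundle` list with one entry per scenario (`outcomes`,
#'   `incremental`, `icer`, `verdict`), plus optional `psa` and `budget`
#'   sections and the `params` used.
#' @export
#' @examples
#' b <- run_pipeline(psa_draws = 0, budget = FALSE)
#' b$scenarios$base_case$incremental$delta_cost   # -1794
run_pipeline <- function(params = NULL,
                         scenarios = c("base_case", "conservative"),
                         seed = 1L, psa_draws = 0L, budget = TRUE,
                         budget_distance_km = 20) {
  if (is.null(params)) params <- load_parameters()
  stopifnot(inherits(params, "cea_parameters"))
  band <- c(params$economics$threshold_low, params$economics$threshold_high)
  per_scenario <- lapply(scenarios, function(nm) {
    sc <- resolve_scenario(params, nm)
    prim <- strategy_outcome(sc, "primary_care_algorithm")
    hosp <- strategy_outcome(sc, "hospital_standard")
    inc <- incremental(prim, hosp)
    ic <- icer(inc$delta_cost, inc$delta_qaly)
    list(
      scenario = nm,
      outcomes = list(primary_care_algorithm = prim,
                      hospital_standard = hosp),
      incremental = inc,
      icer = ic,
      verdict = verdict(ic, band)
    )
  })
  names(per_scenario) <- scenarios
  bundle <- list(params = params, scenarios = per_scenario, seed = seed)
  if (psa_draws > 0L) {
    dists <- assign_distributions(params)
    bundle$psa <- run_psa(dists, psa_draws, seed = seed, params = params)
    bundle$ceac <- ceac(bundle$psa)
  }
  if (budget) {
    cov <- coverage_table()
    tier <- coverage_at(cov, budget_distance_km)
    elig <- eligible_patients(coverage_fraction = tier$fraction)
    savings <- lapply(per_scenario, function(s) {
      annual_savings(elig$discharged, -s$incremental$delta_cost)
    })
    bundle$budget <- list(
      distance_km = budget_distance_km,
      coverage = tier,
      eligible = elig,
      savings = savings
    )
  }
  class(bundle) <- "cea_bundle"
  bundle
}

#' Render the comparison table of the two strategies
#'
#' Builds the published-style comparison table: one row per cost
#' component plus TOTAL, LOS and QALY rows; one column per scenario and
#' arm plus a difference column computed from the rendered values.
#' Costs are whole EUR, QALYs rounded to 5 decimals, LOS to 1 decimal.
#'
#' @param bundle A `cea_bundle` from [run_pipeline()] containing both
#'   scenarios.
#' @param path Optional CSV output path.
#' @return The table as a data frame (invisibly written to `path` when
#'   given).
#' @export
#' @examples
#' tab <- render_report(run_pipeline(psa_draws = 0, budget = FALSE))
#' tab[tab$row == "TOTAL", ]
render_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "cea_bundle"))
  need <- c("base_case", "conservative")
  have <- intersect(need, names(bundle$scenarios))
  if (length(have) == 0L) {
    warning("bundle contains no renderable scenarios; nothing written")
    return(invisible(NULL))
  }
  comp_labels <- c("ems_to_primary", "consultation", "algorithm_addon",
                   "ems_to_hospital", "hospital_drg")
  cell <- function(scenario, arm, label) {
    sc <- bundle$scenarios[[scenario]]
    if (is.null(sc)) return(NA_real_)
    comps <- sc$outcomes[[arm]]$cost$components
    i <- match(label, comps$label)
    if (is.na(i)) NA_real_ else comps$expected[i]
  }
  num_row <- function(f) {
    vapply(c("conservative", "base_case"), function(scn) {
      vapply(c("primary_care_algorithm", "hospital_standard"),
             function(arm) f(scn, arm), numeric(1))
    }, numeric(2))
  }
  rows <- list()
  for (lbl in comp_labels) {
    m <- num_row(function(scn, arm) cell(scn, arm, lbl))
    rows[[lbl]] <- as.vector(m)
  }
  rows[["TOTAL"]] <- as.vector(num_row(function(scn, arm) {
    s <- bundle$scenarios[[scn]]
    if (is.null(s)) NA_real_ else s$outcomes[[arm]]$cost$total
  }))
  rows[["LOS_h"]] <- as.vector(num_row(function(scn, arm) {
    s <- bundle$scenarios[[scn]]
    if (is.null(s)) NA_real_ else round(s$outcomes[[arm]]$mean_los_h, 1)
  }))
  rows[["QALY"]] <- as.vector(num_row(function(scn, arm) {
    s <- bundle$scenarios[[scn]]
    if (is.null(s)) NA_real_ else round(s$outcomes[[arm]]$qaly$total, 5)
  }))
  tab <- data.frame(
    row = names(rows),
    primary_conservative = vapply(rows, `[`, numeric(1), 1L),
    hospital_conservative = vapply(rows, `[`, numeric(1), 2L),
    primary_base = vapply(rows, `[`, numeric(1), 3L),
    hospital_base = vapply(rows, `[`, numeric(1), 4L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # difference column: primary minus hospital on the rendered values
  tab$difference_conservative <- tab$primary_conservative -
    tab$hospital_conservative
  tab$difference_base <- tab$primary_base - tab$hospital_base
  na0 <- is.na(tab$primary_conservative) & !is.na(tab$hospital_conservative)
  tab$difference_conservative[na0] <- -tab$hospital_conservative[na0]
  tab$difference_base[is.na(tab$primary_base) & !is.na(tab$hospital_base)] <-
    -tab$hospital_base[is.na(tab$primary_base) & !is.na(tab$hospital_base)]
  na1 <- !is.na(tab$primary_conservative) & is.na(tab$hospital_conservative)
  tab$difference_conservative[na1] <- tab$primary_conservative[na1]
  nb1 <- !is.na(tab$primary_base) & is.na(tab$hospital_base)
  tab$difference_base[nb1] <- tab$primary_base[nb1]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  tab
}

#' @export
print.cea_bundle <- function(x, ...) {
  cat("<cea_bundle> scenarios:", paste(names(x$scenarios), collapse = ", "),
      "\n")
  for (nm in names(x$scenarios)) {
    s <- x$scenarios[[nm]]
    cat(sprintf("  %-13s delta cost EUR %6d; delta QALY %+.5f; %s\n",
                nm, s$incremental$delta_cost, s$incremental$delta_qaly,
                s$icer$quadrant))
  }
  if (!is.null(x$psa)) {
    cat("  PSA:", x$psa$n_draws, "draws, mean delta cost EUR",
        round(x$psa$mean_delta_cost, 1), "\n")
  }
  if (!is.null(x$budget)) {
    cat("  budget impact at", x$budget$distance_km, "km: discharged",
        x$budget$eligible$discharged, "/ year\n")
  }
  invisible(x)
}
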