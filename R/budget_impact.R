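#' National laboratory-catchment coverage table
#'
#' Step-function coverage of the Norwegian population (n = 5,367,580 in
#' 2020) by distance from an out-of-hours clinic to the nearest hospital
#' with an available hs-cTn assay. The shipped table carries the two
#' published anchor tiers — clinics on hospital grounds (31.4%, 1.7
#' million) and clinics within 20 km of a lab (74.7%, 4.0 million) —
#' and accepts additional tiers from CSV.
#'
#' @param path Optional CSV with columns `distance_km`, `fraction` and
#'   optionally `population`; defaults to the shipped anchor table.
#' @param national_population National population count.
#' @return A `coverage_table` data frame (`distance_km`, `fraction`,
#'   `population`), sorted by distance, with the national population as
#'   attribute `national_population`.
#' @export
#' @examples
#' coverage_table()
coverage_table <- function(path = NULL, national_population = 5367580) {
  if (is.null(path)) {
    path <- system.file("extdata", "coverage_norway.csv",
                        package = "troponinCEA", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("distance_km", "fraction") %in% names(tab))) {
    stop("coverage CSV needs columns distance_km and fraction",
         call. = FALSE)
  }
  tab <- tab[order(tab$distance_km), , drop = FALSE]
  if (any(tab$fraction < 0 | tab$fraction > 1)) {
    stop("coverage fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(tab$fraction)) {
    stop("coverage fraction must be non-decreasing in distance",
         call. = FALSE)
  }
  if (is.null(tab$population)) {
    tab$population <- round(tab$fraction * national_population)
  }
  attr(tab, "national_population") <- national_population
  class(tab) <- c("coverage_table", "data.frame")
  tab
}

#' Population coverage at a given distance
#'
#' Step-function lookup: the largest listed tier whose distance threshold
#' does not exceed the query distance. Distances below the smallest
#' threshold fall back to the on-site tier; distances beyond the table
#' maximum return the largest tier.
#'
#' @param table A `coverage_table`.
#' @param distance_km Query distance in km (>= 0).
#' @return List with `fraction` and `population`.
#' @export
#' @examples
#' coverage_at(coverage_table(), 20)$fraction  # 0.747
coverage_at <- function(table, distance_km) {
  stopifnot(inherits(table, "coverage_table"))
  if (distance_km < 0) stop("`distance_km` must be >= 0", call. = FALSE)
  idx <- findInterval(distance_km, table$distance_km)
  idx <- max(idx, 1L)
  list(fraction = table$fraction[idx], population = table$population[idx])
}

#' Eligible patient counts at national scale
#'
#' Applies catchment coverage and the observed triage split to the annual
#' number of non-specific chest-pain admissions referred after an
#' out-of-hours assessment (7613 in the national registry year used).
#' Assessed patients are rounded first; the discharged count is taken as
#' assessed minus hospitalised so the split always conserves the total.
#'
#' @param annual_admissions Annual OOH-referred non-specific chest-pain
#'   admissions; default 7613.
#' @param coverage_fraction Fraction of those with a clinic within reach
#'   of an hs-cTn lab, in \[0, 1\].
#' @param admit_fraction Fraction hospitalised after triage; default 0.132.
#' @return List with `assessed`, `hospitalised`, `discharged` counts.
#' @export
#' @examples
#' eligible_patients(7613, 0.747)  # 5687 -> 751 / 4936
eligible_patients <- function(annual_admissions = 7613,
                              coverage_fraction,
                              admit_fraction = 0.132) {
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    stop("`coverage_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (admit_fraction < 0 || admit_fraction > 1) {
    stop("`admit_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (annual_admissions < 0) {
    stop("`annual_admissions` must be non-negative", call. = FALSE)
  }
  assessed <- round(annual_admissions * coverage_fraction)
  hospitalised <- round(assessed * admit_fraction)
  list(
    assessed = assessed,
    hospitalised = hospitalised,
    discharged = assessed - hospitalised
  )
}

#' Annual system-level savings
#'
#' Product of the number of patients discharged from primary care (and so
#' not admitted) and the per-patient cost reduction, also expressed in
#' millions of EUR rounded to one decimal.
#'
#' @param discharged Annual discharged count (>= 0).
#' @param saving_per_patient Per-patient saving in EUR (>= 0).
#' @return List with `total_eur` and `millions` (1 d.p.).
#' @export
#' @examples
#' annual_savings(4936, 1672)$millions  # 8.3
annual_savings <- function(discharged, saving_per_patient) {
  if (discharged < 0 || saving_per_patient < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  total <- discharged * saving_per_patient
  list(total_eur = total, millions = round(total / 1e6, 1))
}
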