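#' Assign sampling distributions to the base-case parameters
#'
#' Builds moment-matched sampling distributions for probabilistic
#' sensitivity analysis over the base-case model: probabilities get beta
#' distributions, unit costs gamma, and LOS means normal truncated at
#' zero, each matched to (mean, SE). Where no standard error is supplied
#' the default policy takes SE = 20% of the mean. Any parameter can be
#' pinned with family `"fixed"`.
#'
#' @param params A `cea_parameters` object supplying the means.
#' @param uncertainty_policy List with `rel_se` (default 0.2) and an
#'   optional named `se` list of per-parameter standard errors, and an
#'   optional named `family` list of per-parameter family overrides.
#' @return A named list of distribution specs (class `psa_distributions`),
#'   each with `family`, `mean`, `se`, and family parameters.
#' @export
#' @examples
#' d <- assign_distributions(default_parameters())
#' d$drg_mean$family  # "gamma"
assign_distributions <- function(params = default_parameters(),
                                 uncertainty_policy = list(rel_se = 0.2)) {
  rel <- uncertainty_policy$rel_se
  if (is.null(rel)) rel <- 0.2
  se_over <- uncertainty_policy$se
  fam_over <- uncertainty_policy$family
  co <- params$cost
  ti <- params$time

  means <- c(
    ems_cost_per_transport = co$ems_cost_per_transport,
    p_ambulance_to_primary = co$p_ambulance_to_primary,
    p_ambulance_to_hospital = co$p_ambulance_to_hospital_base,
    consultation_cost = co$consultation_cost,
    algorithm_lab_cost = co$algorithm_lab_cost,
    personnel_cost = co$personnel_cost_wage,
    outpatient_referral_cost = co$outpatient_referral_cost,
    drg_mean = co$drg_total / co$n_hospital_cohort,
    los_primary_mean_h = ti$los_primary_base_mean_h,
    los_hospital_mean_h = ti$los_hospital_mean_h,
    waiting_utility_decrement = params$utility$waiting_utility_decrement
  )
  default_family <- c(
    ems_cost_per_transport = "gamma",
    p_ambulance_to_primary = "beta",
    p_ambulance_to_hospital = "beta",
    consultation_cost = "gamma",
    algorithm_lab_cost = "gamma",
    personnel_cost = "gamma",
    outpatient_referral_cost = "gamma",
    drg_mean = "gamma",
    los_primary_mean_h = "normal",
    los_hospital_mean_h = "normal",
    waiting_utility_decrement = "beta"
  )
  dists <- lapply(names(means), function(key) {
    mu <- means[[key]]
    se <- if (!is.null(se_over[[key]])) se_over[[key]] else rel * mu
    family <- if (!is.null(fam_over[[key]])) fam_over[[key]]
              else default_family[[key]]
    make_distribution(key, family, mu, se)
  })
  names(dists) <- names(means)
  structure(dists, class = "psa_distributions")
}

# one moment-matched distribution spec
make_distribution <- function(key, family, mean, se) {
  family <- match.arg(family, c("beta", "gamma", "normal", "fixed"))
  d <- list(key = key, family = family, mean = mean, se = se)
  if (family == "beta") {
    if (mean < 0 || mean > 1) {
      stop("beta family requires a mean in [0, 1] for ", key, call. = FALSE)
    }
    if (se > 0) {
      if (mean %in% c(0, 1)) {
        stop("infeasible beta moment match for ", key,
             ": mean on the boundary with positive SE", call. = FALSE)
      }
      nu <- mean * (1 - mean) / se^2 - 1
      if (nu <= 0) {
        stop("infeasible beta moment match for ", key,
             ": variance too large", call. = FALSE)
      }
      d$shape1 <- mean * nu
      d$shape2 <- (1 - mean) * nu
    } else {
      d$family <- "fixed"
    }
  } else if (family == "gamma") {
    if (mean < 0) {
      stop("gamma family requires a non-negative mean for ", key,
           call. = FALSE)
    }
    if (se > 0 && mean > 0) {
      d$shape <- (mean / se)^2
      d$rate <- d$shape / mean
    } else {
      d$family <- "fixed"
    }
  } else if (family == "normal") {
    if (se == 0) d$family <- "fixed"
  }
  d
}

# draw n values; truncated-at-zero families use rejection resampling so
# the matched moments stay interpretable; rejections are counted
sample_distribution <- function(d, n) {
  if (d$family == "fixed" || n == 0L) {
    return(list(values = rep(d$mean, n), rejected = 0L))
  }
  draw <- switch(d$family,
    beta = function(m) stats::rbeta(m, d$shape1, d$shape2),
    gamma = function(m) stats::rgamma(m, shape = d$shape, rate = d$rate),
    normal = function(m) stats::rnorm(m, d$mean, d$se)
  )
  values <- draw(n)
  rejected <- 0L
  bad <- which(values < 0)
  while (length(bad)) {
    rejected <- rejected + length(bad)
    values[bad] <- draw(length(bad))
    bad <- bad[values[bad] < 0]
  }
  list(values = values, rejected = rejected)
}

# unrounded base-case incremental pipeline evaluated at one parameter set;
# whole-EUR rounding is a reporting convention and is not applied here
psa_evaluate <- function(par, hours_per_year = 8766) {
  addon <- par[["algorithm_lab_cost"]] + par[["personnel_cost"]] +
    par[["outpatient_referral_cost"]]
  delta_cost <- addon -
    par[["p_ambulance_to_hospital"]] * par[["ems_cost_per_transport"]] -
    par[["drg_mean"]]
  delta_qaly <- (par[["los_hospital_mean_h"]] - par[["los_primary_mean_h"]]) *
    par[["waiting_utility_decrement"]] / hours_per_year
  c(delta_cost = delta_cost, delta_qaly = delta_qaly)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty through the base-case
#' incremental pipeline: each draw samples every parameter from its
#' assigned distribution and re-evaluates the incremental cost and QALY
#' difference (primary care minus hospital, unrounded). Out-of-range
#' draws are rejected and resampled, with the rejection count logged in
#' the result. Fully deterministic for a given seed.
#'
#' @param dists A `psa_distributions` set.
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @param params A `cea_parameters` object (supplies `hours_per_year`).
#' @return A `psa_result` list: `n_draws`, `seed`, `draws` (data frame of
#'   per-draw parameter values, `delta_cost`, `delta_qaly`), `mean_delta_cost`,
#'   `mean_delta_qaly`, `n_rejected`.
#' @export
#' @examples
#' d <- assign_distributions(default_parameters())
#' res <- run_psa(d, n_draws = 200, seed = 11)
#' res$mean_delta_cost
run_psa <- function(dists, n_draws, seed = 1L,
                    params = default_parameters()) {
  stopifnot(inherits(dists, "psa_distributions"))
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("`n_draws` must be >= 1", call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n_rejected <- 0L
  samples <- lapply(dists, function(d) {
    s <- sample_distribution(d, n_draws)
    n_rejected <<- n_rejected + s$rejected
    s$values
  })
  par_mat <- do.call(cbind, samples)
  hpy <- params$time$hours_per_year
  inc <- t(apply(par_mat, 1L, psa_evaluate, hours_per_year = hpy))
  draws <- cbind(as.data.frame(par_mat), as.data.frame(inc))
  structure(
    list(
      n_draws = n_draws,
      seed = as.integer(seed),
      draws = draws,
      mean_delta_cost = mean(draws$delta_cost),
      mean_delta_qaly = mean(draws$delta_qaly),
      n_rejected = n_rejected
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_draws, " draws (seed ", x$seed, ", ",
      x$n_rejected, " rejected-and-resampled)\n",
      "  mean delta cost: EUR ", round(x$mean_delta_cost, 1), "\n",
      "  mean delta QALY: ", signif(x$mean_delta_qaly, 4), "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the probability of cost-effectiveness
#' is the fraction of PSA draws with positive net monetary benefit,
#' `lambda * delta_qaly - delta_cost > 0`.
#'
#' @param psa_result A `psa_result`.
#' @param lambda_grid Non-negative willingness-to-pay grid (EUR/QALY);
#'   default 0 to 150,000 in 1,000-EUR steps.
#' @return Data frame with columns `lambda` and `probability`.
#' @export
#' @examples
#' d <- assign_distributions(default_parameters())
#' head(ceac(run_psa(d, 500, seed = 3), c(0, 25600, 76900)))
ceac <- function(psa_result, lambda_grid = seq(0, 150000, by = 1000)) {
  stopifnot(inherits(psa_result, "psa_result"))
  if (length(lambda_grid) == 0L || any(lambda_grid < 0)) {
    stop("`lambda_grid` must be non-empty and non-negative", call. = FALSE)
  }
  if (psa_result$n_draws == 0L || nrow(psa_result$draws) == 0L) {
    stop("PSA result contains no draws", call. = FALSE)
  }
  dc <- psa_result$draws$delta_cost
  dq <- psa_result$draws$delta_qaly
  prob <- vapply(lambda_grid,
                 function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}
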