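# Probabilistic sensitivity analysis: one parameter draw per Monte Carlo
# iteration. Relative risks are lognormal (median at the point estimate,
# log-sd fitted to the 95% CI width); the real-world effectiveness
# reduction likewise, truncated below 1; coverages are beta with the point
# estimate as mean; unit costs gamma; the severity split Dirichlet centred
# on the input split.

Z975 <- stats::qnorm(0.975)

# log-sd such that a lognormal's 2.5/97.5 quantile ratio matches hi/lo
lognormal_sigma <- function(lo, hi) {
  if (hi <= lo) return(0)
  log(hi / lo) / (2 * Z975)
}

rlnorm_ci <- function(n, median, lo, hi) {
  sigma <- lognormal_sigma(lo, hi)
  if (sigma == 0) return(rep(median, n))   # degenerate CI -> point mass
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma)
}

rbeta_mean <- function(n, mean, concentration) {
  if (mean <= 0 || mean >= 1 || !is.finite(concentration)) {
    return(rep(mean, n))
  }
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

rgamma_cv <- function(n, mean, cv) {
  if (mean <= 0 || cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

rdirichlet1 <- function(alpha) {
  # single Dirichlet draw; zero-weight components stay exactly zero
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Draw one sampled parameter set
#'
#' Produces the per-iteration parameter draw of the probabilistic
#' sensitivity analysis. Relative risks are drawn from lognormal
#' distributions whose median equals the point estimate and whose 2.5/97.5
#' percent quantiles match the published 95% CI (log-sd fitted from the CI
#' width), clamped to (0, 1.5]. The real-world effectiveness reduction is
#' drawn the same way from its CI and truncated to [0, 1). Coverages come
#' from beta distributions with mean at the point estimate, unit costs from
#' gamma distributions with a configurable coefficient of variation, and
#' the severity split from a Dirichlet centred on the input split. One
#' shared real-world-reduction draw is used for both oral-iron
#' interventions within a simulation.
#'
#' @param specs Named list of `intervention_spec` objects.
#' @param config A `cea_config`.
#' @param severity_split The country's severity split to centre on.
#' @param evidence Optional pre-drawn evidence-level parameters from
#'   [sample_evidence()]. Effectiveness estimates come from global trial
#'   evidence, so within one Monte Carlo iteration the same draw should
#'   apply to every country; country-level parameters (coverage, cost,
#'   severity) are always drawn here.
#' @return A list of class `sampled_params` with named vectors `rr`,
#'   `coverage_current`, `coverage_max`, `unit_cost`, scalar
#'   `real_world_reduction` and 3-vector `severity_split`.
#' @export
sample_params <- function(specs, config,
                          severity_split = c(0.6, 0.35, 0.05),
                          evidence = NULL) {
  ids <- names(specs)
  if (is.null(evidence)) evidence <- sample_evidence(specs, config)
  rr <- evidence$rr[ids]
  rwr <- evidence$real_world_reduction
  cov_cur <- vapply(specs, function(s) {
    clamp(rbeta_mean(1, s$coverage_current, config$coverage_concentration),
          0, 1)
  }, 0)
  cov_max <- vapply(specs, function(s) {
    clamp(rbeta_mean(1, s$coverage_max, config$coverage_concentration), 0, 1)
  }, 0)
  cost <- vapply(specs, function(s) {
    rgamma_cv(1, s$unit_cost, config$cost_cv)
  }, 0)
  sev <- if (is.finite(config$severity_concentration)) {
    rdirichlet1(severity_split * config$severity_concentration)
  } else {
    severity_split
  }
  structure(list(
    rr = stats::setNames(rr, ids),
    real_world_reduction = rwr,
    coverage_current = stats::setNames(cov_cur, ids),
    coverage_max = stats::setNames(cov_max, ids),
    unit_cost = stats::setNames(cost, ids),
    severity_split = sev
  ), class = "sampled_params")
}

#' Draw the evidence-level parameters of one iteration
#'
#' Relative risks and the real-world effectiveness reduction are informed
#' by global trial evidence, not by country data; one draw per Monte Carlo
#' iteration is shared by every country (and the reduction draw by both
#' oral-iron interventions).
#'
#' @inheritParams sample_params
#' @return List with named vector `rr` and scalar `real_world_reduction`.
#' @export
sample_evidence <- function(specs, config) {
  rr <- vapply(specs, function(s) {
    clamp(rlnorm_ci(1, s$rr_median, s$rr_ci_low, s$rr_ci_high), 1e-9, 1.5)
  }, 0)
  ci <- config$effectiveness_reduction_ci
  rwr <- clamp(rlnorm_ci(1, config$effectiveness_reduction_median,
                         ci[1], ci[2]), 0, 0.999)
  list(rr = stats::setNames(rr, names(specs)), real_world_reduction = rwr)
}

#' Point-estimate parameter set
#'
#' The degenerate counterpart of [sample_params()]: every parameter fixed at
#' its point estimate. Used for deterministic runs and first-iteration
#' league-table reports.
#'
#' @inheritParams sample_params
#' @return A `sampled_params` list.
#' @export
point_params <- function(specs, config,
                         severity_split = c(0.6, 0.35, 0.05)) {
  ids <- names(specs)
  structure(list(
    rr = stats::setNames(vapply(specs, `[[`, 0, "rr_median"), ids),
    real_world_reduction = config$effectiveness_reduction_median,
    coverage_current = stats::setNames(
      vapply(specs, `[[`, 0, "coverage_current"), ids),
    coverage_max = stats::setNames(
      vapply(specs, `[[`, 0, "coverage_max"), ids),
    unit_cost = stats::setNames(vapply(specs, `[[`, 0, "unit_cost"), ids),
    severity_split = severity_split
  ), class = "sampled_params")
}

#' Resolve the willingness-to-pay threshold for a scenario
#'
#' `cet_gdp1` uses 1 x GDP per capita per DALY averted; `cet_opportunity`
#' the supplied country-specific opportunity-cost threshold (derived from
#' health expenditure and life expectancy; applied to DALYs averted although
#' estimated per QALY); `no_constraint` removes the threshold entirely; the
#' `zero_baseline` scenario keeps the 1 x GDP threshold — it changes the
#' coverage rule, not the willingness to pay.
#'
#' @param profile A `country_profile`.
#' @param scenario Scenario name.
#' @return USD per DALY averted, or `Inf`.
#' @export
cet_for_scenario <- function(profile, scenario) {
  switch(scenario,
    cet_gdp1 = profile$gdp_per_capita,
    cet_opportunity = profile$cet_opportunity,
    no_constraint = Inf,
    zero_baseline = profile$gdp_per_capita,
    stop("unknown scenario: ", scenario))
}
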