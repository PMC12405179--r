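#' Global model configuration
#'
#' Bundles the run-level settings of the target-setting model: number of
#' Monte Carlo simulations, random seed, scenario, disability weights, the
#' real-world effectiveness reduction applied to oral iron supplementation,
#' and the fraction linking non-pregnant to pregnant iron coverage.
#'
#' @param n_sims Number of Monte Carlo simulations (default 1000).
#' @param seed Integer seed governing all randomness of a run.
#' @param scenario One of `"cet_gdp1"` (willingness-to-pay of 1 x GDP per
#'   capita per DALY averted), `"cet_opportunity"` (country-specific
#'   opportunity-cost threshold), `"no_constraint"` (thresholds removed,
#'   every intervention scaled up) or `"zero_baseline"` (current coverage
#'   treated as nil, so the full maximum coverage acts on baseline burden).
#' @param daly_weights Disability weights for mild, moderate and severe
#'   anaemia; defaults are the GBD anaemia weights (0.004, 0.052, 0.149).
#'   Must be strictly increasing, each in (0, 1).
#' @param effectiveness_reduction_median,effectiveness_reduction_ci Median
#'   and 95% CI of the proportional reduction in oral-iron effectiveness at
#'   programmatic scale (defaults 0.38 and (0.21, 0.69)).
#' @param nonpregnant_coverage_fraction Fraction of pregnant-iron coverage
#'   assumed for non-pregnant women (default 0.41).
#' @param coverage_concentration Beta concentration for coverage sampling
#'   (default 50); larger values shrink draws toward the point estimate.
#' @param cost_cv Coefficient of variation of the gamma unit-cost sampling
#'   distribution (default 0.25).
#' @param severity_concentration Dirichlet concentration for severity-split
#'   sampling (default 100).
#'
#' @return A list of class `cea_config`.
#' @export
#' @examples
#' cfg <- cea_config(n_sims = 100, seed = 1)
#' cfg$daly_weights
cea_config <- function(n_sims = 1000L,
                       seed = 1L,
                       scenario = c("cet_gdp1", "cet_opportunity",
                                    "no_constraint", "zero_baseline"),
                       daly_weights = c(mild = 0.004, moderate = 0.052,
                                        severe = 0.149),
                       effectiveness_reduction_median = 0.38,
                       effectiveness_reduction_ci = c(0.21, 0.69),
                       nonpregnant_coverage_fraction = 0.41,
                       coverage_concentration = 50,
                       cost_cv = 0.25,
                       severity_concentration = 100) {
  scenario <- match.arg(scenario)
  if (!is_number(n_sims) || n_sims < 1) {
    stop_validation("n_sims must be a positive integer")
  }
  daly_weights <- unname(as.numeric(daly_weights))
  if (length(daly_weights) != 3L || any(daly_weights <= 0) ||
      any(daly_weights >= 1) || any(diff(daly_weights) <= 0)) {
    stop_validation("daly_weights must be 3 values in (0,1), ",
                    "strictly increasing mild < moderate < severe")
  }
  m <- effectiveness_reduction_median
  ci <- as.numeric(effectiveness_reduction_ci)
  if (!is_number(m) || m <= 0 || m >= 1 ||
      length(ci) != 2L || ci[1] > m || ci[2] < m ||
      any(ci <= 0) || any(ci >= 1)) {
    stop_validation("effectiveness reduction median/CI must lie in (0,1) ",
                    "with ci_low <= median <= ci_high")
  }
  if (!is_number(nonpregnant_coverage_fraction) ||
      nonpregnant_coverage_fraction < 0 || nonpregnant_coverage_fraction > 1) {
    stop_validation("nonpregnant_coverage_fraction must be in [0,1]")
  }
  structure(list(
    n_sims = as.integer(n_sims),
    seed = as.integer(seed),
    scenario = scenario,
    daly_weights = daly_weights,
    effectiveness_reduction_median = m,
    effectiveness_reduction_ci = ci,
    nonpregnant_coverage_fraction = nonpregnant_coverage_fraction,
    coverage_concentration = coverage_concentration,
    cost_cv = cost_cv,
    severity_concentration = severity_concentration
  ), class = "cea_config")
}

#' Read a model configuration from a YAML file
#'
#' Keys mirror the arguments of [cea_config()]; missing keys fall back to
#' the built-in defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cea_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(cea_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
  }
  do.call(cea_config, raw[intersect(names(raw), known)])
}

#' @export
print.cea_config <- function(x, ...) {
  cat("Anaemia CEA configuration\n")
  cat("  scenario:", x$scenario, "  n_sims:", x$n_sims, "  seed:", x$seed, "\n")
  cat("  disability weights (mild/moderate/severe):",
      paste(x$daly_weights, collapse = "/"), "\n")
  cat("  oral-iron real-world reduction:",
      x$effectiveness_reduction_median, sprintf("(95%% CI %.2f-%.2f)",
      x$effectiveness_reduction_ci[1], x$effectiveness_reduction_ci[2]), "\n")
  invisible(x)
}
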