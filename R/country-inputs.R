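# Eligibility mapping is fixed by intervention: who receives the product
# (and so accrues cost) and which anaemic segment can benefit.
#   fortification     received by total population, benefits all anaemic WRA
#   iron_nonpregnant  received by non-pregnant WRA,  benefits non-pregnant anaemic
#   iron_pregnant     received by pregnant women,    benefits pregnant anaemic
#   iptp              received by pregnant women,    benefits pregnant anaemic
#                                                    with malaria
INTERVENTION_IDS <- c("fortification", "iron_nonpregnant",
                      "iron_pregnant", "iptp")

ELIGIBILITY_MAP <- list(
  fortification    = c(receiving = "total_population",
                       benefitting = "all_anaemic"),
  iron_nonpregnant = c(receiving = "all_wra_nonpregnant",
                       benefitting = "nonpregnant_anaemic"),
  iron_pregnant    = c(receiving = "pregnant",
                       benefitting = "pregnant_anaemic"),
  iptp             = c(receiving = "pregnant",
                       benefitting = "pregnant_anaemic_malaria")
)

COUNTRY_COLUMNS <- c("country_id", "name", "region", "income_group",
                     "pop_total", "women_wra", "anaemic_women",
                     "pregnant_women", "pregnant_anaemic",
                     "pregnant_anaemic_malaria",
                     "sev_mild", "sev_moderate", "sev_severe",
                     "gdp_per_capita", "cet_opportunity")

INTERVENTION_COLUMNS <- c("intervention_id", "rr_median", "rr_ci_low",
                          "rr_ci_high", "real_world_adjust",
                          "coverage_current", "coverage_max", "unit_cost")

#' Construct a validated country profile
#'
#' A country profile holds the demographic, epidemiologic and economic
#' inputs the model needs for one country: the anaemic population of women
#' of reproductive age (WRA, 15-49 years), its pregnancy and malaria
#' sub-segments, the severity split of anaemia, GDP per capita and an
#' opportunity-cost cost-effectiveness threshold.
#'
#' Population segments are stored as non-negative reals (they are modelled
#' quantities, not census integers). A single severity split is assumed to
#' apply to pregnant and non-pregnant anaemic women alike.
#'
#' @param country_id Short unique identifier.
#' @param name Country name.
#' @param region World Bank region label.
#' @param income_group World Bank income group label.
#' @param pop_total Total population (all ages, both sexes).
#' @param women_wra Women aged 15-49.
#' @param anaemic_women Anaemic women aged 15-49.
#' @param pregnant_women Pregnant women.
#' @param pregnant_anaemic Pregnant anaemic women.
#' @param pregnant_anaemic_malaria Pregnant anaemic women with malaria.
#' @param severity_split Fractions (mild, moderate, severe) of anaemic
#'   women; must sum to 1 within 1e-9.
#' @param gdp_per_capita GDP per capita, USD/year; must be positive.
#' @param cet_opportunity Opportunity-cost willingness-to-pay threshold,
#'   USD per DALY averted; non-negative.
#'
#' @return A list of class `country_profile`.
#' @export
#' @examples
#' country_profile("AAA", "Examplia", "South Asia", "LMIC",
#'   pop_total = 4e6, women_wra = 1e6, anaemic_women = 3e5,
#'   pregnant_women = 8e4, pregnant_anaemic = 3e4,
#'   pregnant_anaemic_malaria = 6e3,
#'   severity_split = c(0.6, 0.35, 0.05),
#'   gdp_per_capita = 2000, cet_opportunity = 750)
country_profile <- function(country_id, name = country_id,
                            region = "unspecified",
                            income_group = "unspecified",
                            pop_total, women_wra, anaemic_women,
                            pregnant_women, pregnant_anaemic,
                            pregnant_anaemic_malaria,
                            severity_split, gdp_per_capita,
                            cet_opportunity) {
  p <- structure(list(
    country_id = as.character(country_id),
    name = as.character(name),
    region = as.character(region),
    income_group = as.character(income_group),
    pop_total = as.numeric(pop_total),
    women_wra = as.numeric(women_wra),
    anaemic_women = as.numeric(anaemic_women),
    pregnant_women = as.numeric(pregnant_women),
    pregnant_anaemic = as.numeric(pregnant_anaemic),
    pregnant_anaemic_malaria = as.numeric(pregnant_anaemic_malaria),
    severity_split = unname(as.numeric(severity_split)),
    gdp_per_capita = as.numeric(gdp_per_capita),
    cet_opportunity = as.numeric(cet_opportunity)
  ), class = "country_profile")
  validate_country(p)
  p
}

#' Validate a country profile
#'
#' Checks the structural invariants of the population segments (nesting of
#' anaemic, pregnant and malaria sub-populations), the severity split and
#' the economic inputs. Called by every constructor and reader; exported so
#' externally assembled profiles can be checked too.
#'
#' @param p A `country_profile`.
#' @return `p`, invisibly, if valid; otherwise a validation error naming the
#'   country and offending field.
#' @export
validate_country <- function(p) {
  id <- p$country_id %||% "<unknown>"
  fail <- function(field, why) {
    stop_validation("country '", id, "': ", field, " ", why)
  }
  num <- c("pop_total", "women_wra", "anaemic_women", "pregnant_women",
           "pregnant_anaemic", "pregnant_anaemic_malaria",
           "gdp_per_capita", "cet_opportunity")
  for (f in num) {
    v <- p[[f]]
    if (!is_number(v) || v < 0) fail(f, "must be a non-negative number")
  }
  if (p$women_wra > p$pop_total) fail("women_wra", "exceeds pop_total")
  if (p$anaemic_women > p$women_wra) fail("anaemic_women", "exceeds women_wra")
  if (p$pregnant_women > p$women_wra) {
    fail("pregnant_women", "exceeds women_wra")
  }
  if (p$pregnant_anaemic > min(p$anaemic_women, p$pregnant_women)) {
    fail("pregnant_anaemic", "exceeds anaemic_women or pregnant_women")
  }
  if (p$pregnant_anaemic_malaria > p$pregnant_anaemic) {
    fail("pregnant_anaemic_malaria", "exceeds pregnant_anaemic")
  }
  s <- p$severity_split
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    fail("severity_split", "must be 3 fractions in [0,1]")
  }
  if (abs(sum(s) - 1) > 1e-9) fail("severity_split", "must sum to 1")
  if (p$gdp_per_capita <= 0) fail("gdp_per_capita", "must be positive")
  invisible(p)
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile> %s (%s) | %s, %s\n", x$name, x$country_id,
              x$region, x$income_group))
  cat(sprintf("  WRA %.0f, anaemic %.0f (prevalence %.1f%%), pregnant %.0f\n",
              x$women_wra, x$anaemic_women,
              100 * x$anaemic_women / max(x$women_wra, 1), x$pregnant_women))
  cat(sprintf("  GDP/capita $%.0f, opportunity CET $%.0f/DALY\n",
              x$gdp_per_capita, x$cet_opportunity))
  invisible(x)
}

#' Construct a validated intervention specification
#'
#' Holds one intervention's effectiveness (relative risk of remaining
#' anaemic, with 95% CI), whether the real-world effectiveness reduction
#' applies, current and maximum coverage of the eligible population, and
#' the unit cost per person in the receiving population per year (2023
#' USD). The receiving and benefitting segments are fixed by
#' `intervention_id` (see [default_interventions()]).
#'
#' @param intervention_id One of `"fortification"`, `"iron_nonpregnant"`,
#'   `"iron_pregnant"`, `"iptp"`.
#' @param rr_median,rr_ci_low,rr_ci_high Relative risk of remaining anaemic
#'   and its 95% CI; each in (0, 1.5] with low <= median <= high.
#' @param real_world_adjust Whether the scale-up effectiveness reduction is
#'   applied (true only for the oral-iron interventions).
#' @param coverage_current,coverage_max Fractions of the eligible population
#'   currently and maximally reachable, in [0, 1].
#' @param unit_cost USD per person in the receiving population per year.
#'
#' @return A list of class `intervention_spec`.
#' @export
intervention_spec <- function(intervention_id, rr_median, rr_ci_low,
                              rr_ci_high, real_world_adjust,
                              coverage_current, coverage_max, unit_cost) {
  intervention_id <- match.arg(intervention_id, INTERVENTION_IDS)
  s <- structure(list(
    intervention_id = intervention_id,
    rr_median = as.numeric(rr_median),
    rr_ci_low = as.numeric(rr_ci_low),
    rr_ci_high = as.numeric(rr_ci_high),
    real_world_adjust = isTRUE(as.logical(real_world_adjust)),
    coverage_current = as.numeric(coverage_current),
    coverage_max = as.numeric(coverage_max),
    unit_cost = as.numeric(unit_cost),
    receiving_segment = ELIGIBILITY_MAP[[intervention_id]][["receiving"]],
    benefitting_segment = ELIGIBILITY_MAP[[intervention_id]][["benefitting"]]
  ), class = "intervention_spec")
  validate_intervention(s)
  s
}

#' Validate an intervention specification
#' @param s An `intervention_spec`.
#' @return `s` invisibly if valid, else a validation error.
#' @export
validate_intervention <- function(s) {
  id <- s$intervention_id %||% "<unknown>"
  fail <- function(field, why) {
    stop_validation("intervention '", id, "': ", field, " ", why)
  }
  rr <- c(s$rr_ci_low, s$rr_median, s$rr_ci_high)
  if (any(!is.finite(rr)) || any(rr <= 0) || any(rr > 1.5)) {
    fail("rr", "values must lie in (0, 1.5]")
  }
  if (s$rr_ci_low > s$rr_median || s$rr_median > s$rr_ci_high) {
    fail("rr", "must satisfy ci_low <= median <= ci_high")
  }
  for (f in c("coverage_current", "coverage_max")) {
    v <- s[[f]]
    if (!is_number(v) || v < 0 || v > 1) fail(f, "must be in [0,1]")
  }
  if (!is_number(s$unit_cost) || s$unit_cost < 0) {
    fail("unit_cost", "must be non-negative")
  }
  exp_map <- ELIGIBILITY_MAP[[id]]
  if (!identical(s$receiving_segment, exp_map[["receiving"]]) ||
      !identical(s$benefitting_segment, exp_map[["benefitting"]])) {
    fail("eligibility", "segments do not match the fixed mapping")
  }
  invisible(s)
}

#' Coverage of iron supplementation in non-pregnant women
#'
#' Survey data rarely report iron-supplement uptake outside pregnancy;
#' coverage in non-pregnant women is therefore estimated as a fixed fraction
#' (default 0.41, from US survey uptake ratios) of the coverage among
#' pregnant women.
#'
#' @param pregnant_coverage Fraction of pregnant women receiving iron.
#' @param fraction_param Multiplier linking non-pregnant to pregnant
#'   coverage (default 0.41).
#' @return `pregnant_coverage * fraction_param`, clamped to [0, 1].
#' @export
#' @examples
#' derive_nonpregnant_iron_coverage(0.60, 0.41)  # 0.246
derive_nonpregnant_iron_coverage <- function(pregnant_coverage,
                                             fraction_param = 0.41) {
  if (!is_number(pregnant_coverage) || pregnant_coverage < 0 ||
      pregnant_coverage > 1) {
    stop_validation("pregnant_coverage must be in [0,1]")
  }
  if (!is_number(fraction_param) || fraction_param < 0 ||
      fraction_param > 1) {
    stop_validation("fraction_param must be in [0,1]")
  }
  clamp(pregnant_coverage * fraction_param, 0, 1)
}

#' Default intervention specifications
#'
#' The four recommended interventions with their published effectiveness
#' estimates (relative risk of remaining anaemic, from meta-analyses of
#' randomised trials): staple-food fortification with iron RR 0.73
#' (0.55-0.97); IPTp-SP antenatal antimalarials RR 0.90 (0.87-0.93); oral
#' iron in pregnancy RR 0.30 (0.20-0.47); intermittent oral iron in
#' non-pregnant (menstruating) women RR 0.65 (0.49-0.87). The real-world
#' effectiveness reduction applies only to the two oral-iron interventions;
#' fortification and presumptive malaria treatment are less sensitive to
#' compliance and delivery, so their trial effects are used unadjusted.
#'
#' Coverage and unit cost default to zero/zero placeholders and are expected
#' to be overridden per country (from data or the synthetic generator).
#'
#' @param config A `cea_config` (unused by the defaults themselves but
#'   accepted for interface symmetry).
#' @return A named list of four `intervention_spec` objects.
#' @export
default_interventions <- function(config = cea_config()) {
  specs <- list(
    fortification = intervention_spec("fortification",
      rr_median = 0.73, rr_ci_low = 0.55, rr_ci_high = 0.97,
      real_world_adjust = FALSE,
      coverage_current = 0, coverage_max = 0, unit_cost = 0),
    iron_nonpregnant = intervention_spec("iron_nonpregnant",
      rr_median = 0.65, rr_ci_low = 0.49, rr_ci_high = 0.87,
      real_world_adjust = TRUE,
      coverage_current = 0, coverage_max = 0, unit_cost = 0),
    iron_pregnant = intervention_spec("iron_pregnant",
      rr_median = 0.30, rr_ci_low = 0.20, rr_ci_high = 0.47,
      real_world_adjust = TRUE,
      coverage_current = 0, coverage_max = 0, unit_cost = 0),
    iptp = intervention_spec("iptp",
      rr_median = 0.90, rr_ci_low = 0.87, rr_ci_high = 0.93,
      real_world_adjust = FALSE,
      coverage_current = 0, coverage_max = 0, unit_cost = 0)
  )
  specs
}

profile_to_row <- function(p) {
  data.frame(country_id = p$country_id, name = p$name, region = p$region,
             income_group = p$income_group, pop_total = p$pop_total,
             women_wra = p$women_wra, anaemic_women = p$anaemic_women,
             pregnant_women = p$pregnant_women,
             pregnant_anaemic = p$pregnant_anaemic,
             pregnant_anaemic_malaria = p$pregnant_anaemic_malaria,
             sev_mild = p$severity_split[1],
             sev_moderate = p$severity_split[2],
             sev_severe = p$severity_split[3],
             gdp_per_capita = p$gdp_per_capita,
             cet_opportunity = p$cet_opportunity,
             stringsAsFactors = FALSE)
}

row_to_profile <- function(r) {
  country_profile(
    country_id = r$country_id, name = r$name, region = r$region,
    income_group = r$income_group, pop_total = r$pop_total,
    women_wra = r$women_wra, anaemic_women = r$anaemic_women,
    pregnant_women = r$pregnant_women, pregnant_anaemic = r$pregnant_anaemic,
    pregnant_anaemic_malaria = r$pregnant_anaemic_malaria,
    severity_split = c(r$sev_mild, r$sev_moderate, r$sev_severe),
    gdp_per_capita = r$gdp_per_capita, cet_opportunity = r$cet_opportunity)
}

#' Read country profiles from CSV or JSON
#'
#' The CSV schema has one row per country with columns
#' `country_id,name,region,income_group,pop_total,women_wra,anaemic_women,
#' pregnant_women,pregnant_anaemic,pregnant_anaemic_malaria,sev_mild,
#' sev_moderate,sev_severe,gdp_per_capita,cet_opportunity`. JSON files hold
#' an array of objects with the same fields. Every row is validated; a
#' violation raises an error naming the country and field. Row order is
#' preserved.
#'
#' @param path Input file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return A list of `country_profile` objects.
#' @export
read_countries <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  missing <- setdiff(COUNTRY_COLUMNS, names(df))
  if (length(missing)) {
    stop("country table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) row_to_profile(df[i, , drop = FALSE]))
}

#' Write country profiles to CSV
#' @param profiles List of `country_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_countries <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, profile_to_row))
  write_atomic(function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read intervention specifications from CSV
#'
#' Columns: `intervention_id,rr_median,rr_ci_low,rr_ci_high,
#' real_world_adjust,coverage_current,coverage_max,unit_cost` plus an
#' optional `country_id`. Rows without `country_id` are global defaults;
#' rows with it override the defaults for that country.
#'
#' @param path Input CSV path.
#' @return A list with `defaults` (named list of `intervention_spec`) and
#'   `overrides` (named list keyed by country_id, each a named list of
#'   specs). Use [specs_for_country()] to resolve a country's table.
#' @export
read_interventions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(INTERVENTION_COLUMNS, names(df))
  if (length(missing)) {
    stop("intervention table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  has_cid <- "country_id" %in% names(df)
  mk <- function(r) {
    intervention_spec(r$intervention_id, r$rr_median, r$rr_ci_low,
                      r$rr_ci_high, r$real_world_adjust,
                      r$coverage_current, r$coverage_max, r$unit_cost)
  }
  defaults <- list()
  overrides <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, , drop = FALSE]
    cid <- if (has_cid && !is.na(r$country_id) && nzchar(r$country_id)) {
      r$country_id
    } else {
      NA_character_
    }
    s <- mk(r)
    if (is.na(cid)) {
      defaults[[s$intervention_id]] <- s
    } else {
      overrides[[cid]][[s$intervention_id]] <- s
    }
  }
  list(defaults = defaults, overrides = overrides)
}

#' Resolve the intervention table for one country
#' @param tables Result of [read_interventions()], or a plain named list of
#'   specs applied to all countries.
#' @param country_id Country identifier.
#' @return Named list of four `intervention_spec` objects.
#' @export
specs_for_country <- function(tables, country_id) {
  if (!is.null(tables$defaults) || !is.null(tables$overrides)) {
    out <- tables$defaults
    ov <- tables$overrides[[country_id]]
    for (id in names(ov)) out[[id]] <- ov[[id]]
  } else {
    out <- tables
  }
  if (!setequal(names(out), INTERVENTION_IDS)) {
    stop("country '", country_id, "' does not resolve to exactly the four ",
         "interventions: got ", paste(names(out), collapse = ", "))
  }
  out[INTERVENTION_IDS]
}

#' Write intervention specifications to CSV
#' @param specs_by_country Named list (by country_id) of named spec lists,
#'   or a single named spec list written without `country_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interventions <- function(specs_by_country, path) {
  spec_row <- function(s, cid = NA_character_) {
    data.frame(intervention_id = s$intervention_id, rr_median = s$rr_median,
               rr_ci_low = s$rr_ci_low, rr_ci_high = s$rr_ci_high,
               real_world_adjust = s$real_world_adjust,
               coverage_current = s$coverage_current,
               coverage_max = s$coverage_max, unit_cost = s$unit_cost,
               country_id = cid, stringsAsFactors = FALSE)
  }
  if (inherits(specs_by_country[[1]], "intervention_spec")) {
    rows <- lapply(specs_by_country, spec_row)
  } else {
    rows <- unlist(lapply(names(specs_by_country), function(cid) {
      lapply(specs_by_country[[cid]], spec_row, cid = cid)
    }), recursive = FALSE)
  }
  df <- do.call(rbind, rows)
  write_atomic(function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  }, path)
}
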