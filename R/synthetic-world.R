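# Synthetic country generator. Emulates the structure of the model's
# real-world inputs (burden surfaces, coverage levels, unit costs, economic
# thresholds) across three broad country archetypes so that the full
# pipeline runs and is tested without any external data. Parameter ranges
# are generator configuration — plausible magnitudes, never estimates.

#' Construct a country archetype
#'
#' An archetype is a band of the between-country heterogeneity the model
#' operates over: anaemia prevalence, the malaria share of pregnant anaemic
#' women, GDP per capita, and per-intervention coverage and unit-cost
#' ranges. Countries are drawn uniformly (GDP log-uniformly) within the
#' archetype's intervals.
#'
#' @param label Archetype name.
#' @param prevalence_range Anaemia prevalence interval among WRA.
#' @param malaria_share_range Share of pregnant anaemic women with malaria.
#' @param gdp_range GDP per capita interval, USD.
#' @param coverage_current_ranges,coverage_max_ranges Named lists of
#'   per-intervention coverage intervals (fractions).
#' @param cost_ranges Named list of per-intervention unit-cost intervals,
#'   USD per person in the receiving population per year.
#' @param region,income_group Labels stamped on generated countries.
#' @return A list of class `archetype`.
#' @export
archetype <- function(label, prevalence_range, malaria_share_range,
                      gdp_range, coverage_current_ranges,
                      coverage_max_ranges, cost_ranges,
                      region = "unspecified", income_group = "unspecified") {
  chk <- function(iv, nm, frac = TRUE) {
    if (length(iv) != 2L || iv[1] > iv[2]) {
      stop_validation("archetype '", label, "': ", nm,
                      " must be an interval lower <= upper")
    }
    if (frac && (iv[1] < 0 || iv[2] > 1)) {
      stop_validation("archetype '", label, "': ", nm, " must lie in [0,1]")
    }
  }
  chk(prevalence_range, "prevalence_range")
  chk(malaria_share_range, "malaria_share_range")
  chk(gdp_range, "gdp_range", frac = FALSE)
  for (id in INTERVENTION_IDS) {
    chk(coverage_current_ranges[[id]], paste0("coverage_current[", id, "]"))
    chk(coverage_max_ranges[[id]], paste0("coverage_max[", id, "]"))
    chk(cost_ranges[[id]], paste0("cost[", id, "]"), frac = FALSE)
  }
  structure(list(label = label, prevalence_range = prevalence_range,
                 malaria_share_range = malaria_share_range,
                 gdp_range = gdp_range,
                 coverage_current_ranges = coverage_current_ranges,
                 coverage_max_ranges = coverage_max_ranges,
                 cost_ranges = cost_ranges, region = region,
                 income_group = income_group), class = "archetype")
}

#' Default archetype set
#'
#' Three archetypes spanning the global burden gradient:
#' `low_income_high_burden` (prevalence 25-60%, substantial malaria,
#' GDP 500-2500), `middle_income` (15-40%, GDP 2500-15000) and
#' `high_income_low_burden` (5-20%, negligible malaria, GDP 15000-80000).
#' Current coverage bands sit below maximum coverage bands, so scale-up
#' headroom is the norm. Unit costs: fortification ~0.10-1.00 USD per
#' capita, oral iron ~2-15 USD per woman-year, IPTp ~1-5 USD per pregnancy.
#'
#' @return Named list of three `archetype` objects.
#' @export
default_archetypes <- function() {
  cov_cur <- function(f, inp, ip, m) {
    list(fortification = f, iron_nonpregnant = inp, iron_pregnant = ip,
         iptp = m)
  }
  costs <- list(fortification = c(0.10, 1.00),
                iron_nonpregnant = c(2, 15),
                iron_pregnant = c(2, 15),
                iptp = c(1, 5))
  list(
    low_income_high_burden = archetype(
      "low_income_high_burden",
      prevalence_range = c(0.25, 0.60),
      malaria_share_range = c(0.10, 0.50),
      gdp_range = c(500, 2500),
      coverage_current_ranges = cov_cur(c(0.05, 0.40), c(0.02, 0.25),
                                        c(0.20, 0.60), c(0.05, 0.40)),
      coverage_max_ranges = cov_cur(c(0.50, 0.90), c(0.55, 0.95),
                                    c(0.55, 0.95), c(0.50, 0.90)),
      cost_ranges = costs,
      region = "Sub-Saharan Africa", income_group = "Low income"),
    middle_income = archetype(
      "middle_income",
      prevalence_range = c(0.15, 0.40),
      malaria_share_range = c(0.00, 0.20),
      gdp_range = c(2500, 15000),
      coverage_current_ranges = cov_cur(c(0.20, 0.60), c(0.05, 0.35),
                                        c(0.40, 0.80), c(0.00, 0.20)),
      coverage_max_ranges = cov_cur(c(0.65, 0.95), c(0.70, 0.98),
                                    c(0.70, 0.98), c(0.30, 0.80)),
      cost_ranges = costs,
      region = "South Asia", income_group = "Lower middle income"),
    high_income_low_burden = archetype(
      "high_income_low_burden",
      prevalence_range = c(0.05, 0.20),
      malaria_share_range = c(0.00, 0.02),
      gdp_range = c(15000, 80000),
      coverage_current_ranges = cov_cur(c(0.40, 0.80), c(0.10, 0.40),
                                        c(0.60, 0.90), c(0.00, 0.05)),
      coverage_max_ranges = cov_cur(c(0.80, 0.99), c(0.85, 0.99),
                                    c(0.85, 0.99), c(0.10, 0.40)),
      cost_ranges = costs,
      region = "Europe & Central Asia", income_group = "High income")
  )
}

runif_iv <- function(iv) stats::runif(1, iv[1], iv[2])
rlogunif_iv <- function(iv) exp(stats::runif(1, log(iv[1]), log(iv[2])))

#' Generate one synthetic country
#'
#' Draws a country profile and its four intervention specifications from an
#' archetype's parameter ranges. The pregnancy rate is drawn in [0.02,
#' 0.18] of WRA; anaemia prevalence among pregnant women is tied to the
#' overall prevalence (within +-30%); the malaria subset follows the
#' archetype's share range; the severity split is Dirichlet centred on
#' (0.6, 0.35, 0.05); the opportunity-cost threshold is a fraction (0.2-0.6)
#' of GDP per capita. Non-pregnant iron coverage is derived from the drawn
#' pregnant-iron coverage via [derive_nonpregnant_iron_coverage()], and its
#' maximum equals antenatal-care (pregnant-iron) maximum coverage.
#'
#' @param arch An `archetype`.
#' @param country_id Identifier for the generated country.
#' @param seed Integer seed; the same seed reproduces the same country.
#' @param config A `cea_config` (supplies the 0.41 coverage fraction).
#' @return A list with `profile` (a `country_profile`) and `specs` (named
#'   list of four `intervention_spec`).
#' @export
generate_country <- function(arch, country_id, seed,
                             config = cea_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pop_total <- rlogunif_iv(c(3e5, 3e8))
  women_wra <- pop_total * stats::runif(1, 0.22, 0.28)
  prevalence <- runif_iv(arch$prevalence_range)
  anaemic <- prevalence * women_wra
  pregnant <- women_wra * stats::runif(1, 0.02, 0.18)
  prev_preg <- clamp(prevalence * stats::runif(1, 0.7, 1.3), 0, 1)
  pregnant_anaemic <- min(prev_preg * pregnant, anaemic, pregnant)
  malaria <- pregnant_anaemic * runif_iv(arch$malaria_share_range)
  sev <- rdirichlet1(c(0.6, 0.35, 0.05) * 60)
  gdp <- rlogunif_iv(arch$gdp_range)
  cet_opp <- gdp * stats::runif(1, 0.2, 0.6)

  profile <- country_profile(
    country_id = country_id,
    name = paste0("Synthetic ", country_id),
    region = arch$region, income_group = arch$income_group,
    pop_total = pop_total, women_wra = women_wra, anaemic_women = anaemic,
    pregnant_women = pregnant, pregnant_anaemic = pregnant_anaemic,
    pregnant_anaemic_malaria = malaria,
    severity_split = sev, gdp_per_capita = gdp, cet_opportunity = cet_opp)

  specs <- default_interventions(config)
  cov_cur <- vapply(INTERVENTION_IDS, function(id) {
    runif_iv(arch$coverage_current_ranges[[id]])
  }, 0)
  cov_max <- vapply(INTERVENTION_IDS, function(id) {
    runif_iv(arch$coverage_max_ranges[[id]])
  }, 0)
  # non-pregnant iron coverage is tied to pregnant-iron coverage; its
  # ceiling is antenatal-care coverage (same as pregnant iron's ceiling)
  cov_cur[["iron_nonpregnant"]] <- derive_nonpregnant_iron_coverage(
    cov_cur[["iron_pregnant"]], config$nonpregnant_coverage_fraction)
  cov_max[["iron_nonpregnant"]] <- cov_max[["iron_pregnant"]]
  for (id in INTERVENTION_IDS) {
    specs[[id]]$coverage_current <- cov_cur[[id]]
    specs[[id]]$coverage_max <- cov_max[[id]]
    specs[[id]]$unit_cost <- runif_iv(arch$cost_ranges[[id]])
    validate_intervention(specs[[id]])
  }
  list(profile = profile, specs = specs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic world
#'
#' Draws `n_countries` countries from a mixture of archetypes. Each country
#' gets its own seed derived deterministically from the world seed and the
#' country id, so adding a country never perturbs the others' draws.
#'
#' @param n_countries Number of countries (the study models 191).
#' @param seed World seed.
#' @param archetype_mix Mixture weights over the archetypes, summing to 1.
#' @param archetypes Named list of `archetype` objects.
#' @param config A `cea_config`.
#' @return A list of class `cea_world` with `countries` (list of
#'   `country_profile`) and `interventions` (named list keyed by country_id,
#'   each a named list of four specs).
#' @export
#' @examples
#' w <- generate_world(5, seed = 1)
#' length(w$countries)
generate_world <- function(n_countries = 191, seed = 1,
                           archetype_mix = c(0.35, 0.40, 0.25),
                           archetypes = default_archetypes(),
                           config = cea_config()) {
  if (!is_number(n_countries) || n_countries < 1) {
    stop_validation("n_countries must be >= 1")
  }
  if (length(archetype_mix) != length(archetypes) ||
      any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9) {
    stop_validation("archetype_mix must be non-negative weights over the ",
                    "archetypes summing to 1")
  }
  ids <- sprintf("SYN%03d", seq_len(n_countries))
  # archetype assignment from the world stream; country internals from
  # per-country streams
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(mix_seed(seed, "world-assignment"))
  assignment <- sample(names(archetypes), n_countries, replace = TRUE,
                       prob = archetype_mix)
  countries <- vector("list", n_countries)
  interventions <- list()
  for (i in seq_len(n_countries)) {
    g <- generate_country(archetypes[[assignment[i]]], ids[i],
                          seed = mix_seed(seed, ids[i]), config = config)
    countries[[i]] <- g$profile
    interventions[[ids[i]]] <- g$specs
  }
  structure(list(countries = countries, interventions = interventions,
                 seed = seed), class = "cea_world")
}

#' @export
print.cea_world <- function(x, ...) {
  prev <- vapply(x$countries, function(p) p$anaemic_women / p$women_wra, 0)
  cat(sprintf("<cea_world> %d synthetic countries (seed %s)\n",
              length(x$countries), x$seed))
  cat(sprintf("  anaemia prevalence: median %.1f%%, range %.1f-%.1f%%\n",
              100 * stats::median(prev), 100 * min(prev), 100 * max(prev)))
  invisible(x)
}

#' Write a world to the countries/interventions CSV dialect
#' @param world A `cea_world`.
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, "countries.csv")
  ipath <- file.path(dir, "interventions.csv")
  write_countries(world$countries, cpath)
  write_interventions(world$interventions, ipath)
  invisible(c(countries = cpath, interventions = ipath))
}

#' Read a world back from countries/interventions CSVs
#' @param countries_path,interventions_path Paths to the two CSV files.
#' @return A `cea_world`.
#' @export
read_world <- function(countries_path, interventions_path) {
  countries <- read_countries(countries_path)
  tables <- read_interventions(interventions_path)
  interventions <- lapply(countries, function(p) {
    specs_for_country(tables, p$country_id)
  })
  names(interventions) <- vapply(countries, `[[`, "", "country_id")
  structure(list(countries = countries, interventions = interventions,
                 seed = NA), class = "cea_world")
}
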