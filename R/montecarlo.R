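# Monte Carlo propagation and aggregation. Every iteration's random draws
# come from a stream seeded by (run seed, country id, iteration), so runs
# are reproducible end to end and scenarios share common random numbers:
# scenario contrasts on the same seed are never noise-dominated.

#' Monte Carlo simulation of one country's reduction target
#'
#' Runs `n_sims` simulations: each draws a parameter set
#' ([sample_params()]), resolves the scenario's willingness-to-pay threshold
#' and coverage rule, executes the league-table loop ([greedy_apply()]) and
#' records the relative reduction in the anaemic population.
#'
#' @param profile A `country_profile`.
#' @param specs Named list of the four `intervention_spec` objects.
#' @param config A `cea_config` (supplies `n_sims`, `seed`, `scenario`).
#' @param scenario Optional scenario override of `config$scenario`.
#' @return Numeric vector of relative reductions (percent), length
#'   `n_sims`; deterministic given seed.
#' @export
run_country_mc <- function(profile, specs, config,
                           scenario = config$scenario) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  zero_base <- identical(scenario, "zero_baseline")
  cet <- cet_for_scenario(profile, scenario)
  out <- numeric(config$n_sims)
  for (iter in seq_len(config$n_sims)) {
    # evidence-level draws (effectiveness) are shared across countries
    # within an iteration; country-level draws use a per-country stream
    set.seed(mix_seed(config$seed, ".evidence", iter))
    ev <- sample_evidence(specs, config)
    set.seed(mix_seed(config$seed, profile$country_id, iter))
    params <- sample_params(specs, config, profile$severity_split,
                            evidence = ev)
    run <- greedy_apply(profile, specs, params, cet, config,
                        zero_baseline = zero_base)
    out[iter] <- run$relative_reduction_pct
  }
  out
}

#' Summarise simulations into a median target with uncertainty interval
#'
#' Median and empirical 2.5/97.5 percentiles across Monte Carlo iterations,
#' using the default linear-interpolation percentile convention
#' (`stats::quantile` type 7).
#'
#' @param sims Numeric vector of per-iteration reductions (percent).
#' @param unit_id Label for the summarised unit.
#' @return A one-row data.frame with `unit_id`, `median_pct`, `ui_low_pct`,
#'   `ui_high_pct`, `n_sims`.
#' @export
summarize_country <- function(sims, unit_id = "unit") {
  if (length(sims) == 0) stop("cannot summarise an empty simulation vector")
  q <- stats::quantile(sims, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  data.frame(unit_id = unit_id, median_pct = q[2], ui_low_pct = q[1],
             ui_high_pct = q[3], n_sims = length(sims),
             stringsAsFactors = FALSE)
}

#' Aggregate country simulations into group and global targets
#'
#' For each Monte Carlo iteration the group target is the (by default
#' unweighted) mean of the member countries' reductions in that iteration;
#' the group summary is the median and 2.5/97.5 percentiles of those
#' per-iteration means. Computing the interval on per-iteration means
#' preserves the cross-country parameter correlation within an iteration;
#' the alternative (`interval = "country_summaries"`) instead averages the
#' countries' own medians and interval bounds.
#'
#' @param sims_matrix Matrix of reductions, countries in rows (rownames =
#'   country ids), iterations in columns.
#' @param grouping `"all"` for a single global group, or a character vector
#'   (one label per country) defining groups.
#' @param weights Optional per-country weights (e.g. WRA populations) for
#'   weighted aggregation; default equal weights — each country counts once.
#' @param interval `"per_iteration"` (default) or `"country_summaries"`.
#' @return A data.frame with one row per group, columns as in
#'   [summarize_country()].
#' @export
aggregate_targets <- function(sims_matrix, grouping = "all", weights = NULL,
                              interval = c("per_iteration",
                                           "country_summaries")) {
  interval <- match.arg(interval)
  n <- nrow(sims_matrix)
  if (identical(grouping, "all")) grouping <- rep("GLOBAL", n)
  stopifnot(length(grouping) == n)
  if (is.null(weights)) weights <- rep(1, n)
  out <- list()
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) == 0) {
      warning("empty group '", g, "' skipped")
      next
    }
    w <- weights[idx] / sum(weights[idx])
    if (interval == "per_iteration") {
      means <- as.numeric(crossprod(w, sims_matrix[idx, , drop = FALSE]))
      out[[g]] <- summarize_country(means, unit_id = g)
    } else {
      per_c <- do.call(rbind, lapply(idx, function(i) {
        summarize_country(sims_matrix[i, ], unit_id = rownames(sims_matrix)[i])
      }))
      out[[g]] <- data.frame(
        unit_id = g,
        median_pct = sum(w * per_c$median_pct),
        ui_low_pct = sum(w * per_c$ui_low_pct),
        ui_high_pct = sum(w * per_c$ui_high_pct),
        n_sims = ncol(sims_matrix), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Set anaemia reduction targets for a world of countries
#'
#' The package's main driver. For every country it propagates parameter
#' uncertainty through the cost-effectiveness league-table model and
#' summarises the achievable relative reduction in the anaemic population
#' of women aged 15-49 as a median with a 95% uncertainty interval; country
#' targets are then averaged (each country counting once) into regional,
#' income-group and global targets.
#'
#' @param world A `cea_world` (from [generate_world()] or [read_world()]).
#' @param config A `cea_config`; `config$scenario` selects the scenario
#'   unless overridden.
#' @param scenario Optional scenario override.
#' @param weighted If `TRUE`, aggregate weighting by each country's WRA
#'   population instead of equal country weights.
#' @return An object of class `anaemia_targets`: list with `sims` (country
#'   x iteration matrix), `countries` (per-country summary data.frame with
#'   region/income metadata), `groups` (regional and income-group
#'   summaries), `global` (one-row summary), `scenario`, `config`.
#' @export
#' @examples
#' w <- generate_world(6, seed = 42)
#' t <- anaemia_targets(w, cea_config(n_sims = 50, seed = 42))
#' print(t)
anaemia_targets <- function(world, config = cea_config(),
                            scenario = config$scenario, weighted = FALSE) {
  ids <- vapply(world$countries, `[[`, "", "country_id")
  sims <- matrix(NA_real_, nrow = length(ids), ncol = config$n_sims,
                 dimnames = list(ids, NULL))
  for (i in seq_along(world$countries)) {
    p <- world$countries[[i]]
    sims[i, ] <- run_country_mc(p, world$interventions[[p$country_id]],
                                config, scenario)
  }
  region <- vapply(world$countries, `[[`, "", "region")
  income <- vapply(world$countries, `[[`, "", "income_group")
  weights <- if (weighted) {
    vapply(world$countries, `[[`, 0, "women_wra")
  } else NULL

  countries <- do.call(rbind, lapply(seq_along(ids), function(i) {
    summarize_country(sims[i, ], unit_id = ids[i])
  }))
  countries$name <- vapply(world$countries, `[[`, "", "name")
  countries$region <- region
  countries$income_group <- income

  groups <- rbind(
    cbind(level = "region",
          aggregate_targets(sims, grouping = region, weights = weights)),
    cbind(level = "income",
          aggregate_targets(sims, grouping = income, weights = weights)))
  global <- aggregate_targets(sims, grouping = "all", weights = weights)

  structure(list(sims = sims, countries = countries, groups = groups,
                 global = global, scenario = scenario, config = config,
                 weighted = weighted),
            class = "anaemia_targets")
}

#' @export
print.anaemia_targets <- function(x, ...) {
  g <- x$global
  cat("Anaemia reduction targets (women aged 15-49)\n")
  cat(sprintf("  scenario: %s | %d countries | %d Monte Carlo simulations\n",
              x$scenario, nrow(x$sims), x$config$n_sims))
  cat(sprintf("  global target: %.1f%% reduction (95%% UI %.1f-%.1f)\n",
              g$median_pct, g$ui_low_pct, g$ui_high_pct))
  cat(sprintf("  national targets range %.1f-%.1f%%\n",
              min(x$countries$median_pct), max(x$countries$median_pct)))
  invisible(x)
}

#' @export
summary.anaemia_targets <- function(object, ...) {
  out <- rbind(
    cbind(level = "global", object$global[, c("unit_id", "median_pct",
          "ui_low_pct", "ui_high_pct", "n_sims")]),
    object$groups[, c("level", "unit_id", "median_pct", "ui_low_pct",
                      "ui_high_pct", "n_sims")],
    cbind(level = "country", object$countries[, c("unit_id", "median_pct",
          "ui_low_pct", "ui_high_pct", "n_sims")]))
  rownames(out) <- NULL
  structure(list(table = out, scenario = object$scenario),
            class = "summary.anaemia_targets")
}

#' @export
print.summary.anaemia_targets <- function(x, ...) {
  cat("Targets by level, scenario", x$scenario, "\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Dot-and-interval plot of national targets
#'
#' Countries ordered by median target; dots are medians, horizontal bars the
#' 95% uncertainty intervals, grouped visually by region. The layout mirrors
#' the way national targets are usually reported: wide between-country
#' variation around a modest global mean.
#'
#' @param x An `anaemia_targets` object.
#' @param max_countries Cap on countries shown (largest-target first).
#' @param ... Passed to `plot.default`.
#' @export
plot.anaemia_targets <- function(x, max_countries = 60, ...) {
  d <- x$countries[order(x$countries$median_pct), , drop = FALSE]
  if (nrow(d) > max_countries) d <- utils::tail(d, max_countries)
  n <- nrow(d)
  cols <- grDevices::hcl.colors(length(unique(d$region)), "Dark 3")
  col <- cols[match(d$region, unique(d$region))]
  graphics::plot(NA, xlim = c(0, max(d$ui_high_pct, 1)), ylim = c(1, n),
                 xlab = "Relative reduction in anaemia prevalence (%)",
                 ylab = "", yaxt = "n", ...)
  graphics::segments(d$ui_low_pct, seq_len(n), d$ui_high_pct, seq_len(n),
                     col = col)
  graphics::points(d$median_pct, seq_len(n), pch = 19, col = col)
  graphics::axis(2, at = seq_len(n), labels = d$unit_id, las = 2,
                 cex.axis = 0.5)
  graphics::abline(v = x$global$median_pct, lty = 2)
  graphics::legend("bottomright", legend = unique(d$region), col = cols,
                   pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}
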