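# Run orchestration and file outputs: targets.csv, league tables, manifest.
# All outputs are written atomically (staged then renamed) so a failed run
# never leaves partial files behind.

scenario_set <- function(scenario) {
  all <- c("cet_gdp1", "cet_opportunity", "no_constraint", "zero_baseline")
  if (identical(scenario, "all")) all else match.arg(scenario, all)
}

league_rows <- function(run, country_id) {
  rows <- list()
  for (it in seq_along(run$league_history)) {
    tab <- run$league_history[[it]]
    applied_here <- if (it <= length(run$applied_sequence)) {
      run$applied_sequence[it]
    } else NA_character_
    for (e in tab) {
      rows[[length(rows) + 1L]] <- data.frame(
        country_id = country_id, iteration = it,
        intervention_id = e$intervention_id,
        delta_coverage = e$delta_coverage,
        cases_averted = e$cases_averted,
        dalys_averted = e$dalys_averted,
        incremental_cost = e$incremental_cost,
        icer = e$icer,
        applied = identical(e$intervention_id, applied_here),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the target-setting pipeline and write its outputs
#'
#' Simulates one or more scenarios over a world of countries and writes:
#' `targets.csv` (country, regional, income-group and global targets),
#' `league.csv` (point-estimate league tables; iteration 1 only unless
#' `verbose_output`), and `manifest.json` (config snapshot, input digests,
#' seed, timestamp, package version) into `out_dir`.
#'
#' @param world A `cea_world`, or `NULL` to read from `countries_path` /
#'   `interventions_path`.
#' @param out_dir Output directory, created if needed.
#' @param config A `cea_config`.
#' @param scenario A scenario name or `"all"`.
#' @param countries_path,interventions_path CSV inputs when `world` is
#'   `NULL`.
#' @param weighted Population-weighted aggregation flag.
#' @param verbose_output Write full per-iteration league histories.
#' @return Named character vector of output paths, invisibly.
#' @export
run_simulation <- function(world = NULL, out_dir, config = cea_config(),
                           scenario = config$scenario,
                           countries_path = NULL, interventions_path = NULL,
                           weighted = FALSE, verbose_output = FALSE) {
  if (is.null(world)) {
    if (is.null(countries_path) || is.null(interventions_path)) {
      stop("supply either a world object or both input CSV paths")
    }
    world <- read_world(countries_path, interventions_path)
  }
  scenarios <- scenario_set(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  target_rows <- list()
  league_tabs <- list()
  for (sc in scenarios) {
    res <- anaemia_targets(world, config, scenario = sc,
                           weighted = weighted)
    block <- rbind(
      cbind(level = "country", res$countries[, c("unit_id", "median_pct",
            "ui_low_pct", "ui_high_pct", "n_sims")]),
      res$groups[, c("level", "unit_id", "median_pct", "ui_low_pct",
                     "ui_high_pct", "n_sims")],
      cbind(level = "global", res$global[, c("unit_id", "median_pct",
            "ui_low_pct", "ui_high_pct", "n_sims")]))
    block$scenario <- sc
    block$seed <- config$seed
    target_rows[[sc]] <- block

    zero_base <- identical(sc, "zero_baseline")
    for (p in world$countries) {
      specs <- world$interventions[[p$country_id]]
      run <- greedy_apply(p, specs,
                          point_params(specs, config, p$severity_split),
                          cet_for_scenario(p, sc), config,
                          zero_baseline = zero_base)
      lr <- league_rows(run, p$country_id)
      if (!verbose_output) lr <- lr[lr$iteration == 1L, , drop = FALSE]
      lr$scenario <- sc
      league_tabs[[paste(sc, p$country_id)]] <- lr
    }
  }
  targets <- do.call(rbind, target_rows)
  targets <- targets[, c("unit_id", "level", "scenario", "median_pct",
                         "ui_low_pct", "ui_high_pct", "n_sims", "seed")]
  rownames(targets) <- NULL
  league <- do.call(rbind, league_tabs)
  rownames(league) <- NULL

  tpath <- file.path(out_dir, "targets.csv")
  lpath <- file.path(out_dir, "league.csv")
  mpath <- file.path(out_dir, "manifest.json")
  write_atomic(function(tmp) {
    utils::write.csv(targets, tmp, row.names = FALSE, quote = FALSE)
  }, tpath)
  write_atomic(function(tmp) {
    utils::write.csv(league, tmp, row.names = FALSE, quote = FALSE)
  }, lpath)

  digests <- if (!is.null(countries_path)) {
    as.list(tools::md5sum(c(countries_path, interventions_path)))
  } else {
    list(world_seed = world$seed)
  }
  manifest <- list(
    package = "anaemiaCEA",
    version = as.character(utils::packageVersion("anaemiaCEA")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    scenarios = scenarios,
    n_sims = config$n_sims,
    n_countries = length(world$countries),
    weighted = weighted,
    config = unclass(config),
    input_digests = digests,
    outputs = c("targets.csv", "league.csv"))
  write_atomic(function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }, mpath)
  invisible(c(targets = tpath, league = lpath, manifest = mpath))
}

#' Print intervention rankings from a completed run
#'
#' Reads `league.csv` from a run directory and prints, per country, the
#' first-iteration ranking of interventions by ICER — the league table a
#' decision maker would consult before any scale-up.
#'
#' @param run_dir Directory written by [run_simulation()].
#' @param scenario Scenario to report (default: first present).
#' @param countries Optional subset of country ids.
#' @return The first-iteration league data.frame, invisibly.
#' @export
league_report <- function(run_dir, scenario = NULL, countries = NULL) {
  lpath <- file.path(run_dir, "league.csv")
  if (!file.exists(lpath)) stop("no league.csv in run directory: ", run_dir)
  league <- utils::read.csv(lpath, stringsAsFactors = FALSE)
  if (is.null(scenario)) scenario <- league$scenario[1]
  d <- league[league$scenario == scenario & league$iteration == 1L, ]
  if (!is.null(countries)) d <- d[d$country_id %in% countries, ]
  if (all(is.infinite(d$icer))) {
    warning("no intervention has any coverage headroom: all ICERs infinite")
  }
  for (cid in unique(d$country_id)) {
    sub <- d[d$country_id == cid, ]
    sub <- sub[order(sub$icer, -sub$dalys_averted, sub$intervention_id), ]
    cat(sprintf("%s [%s]\n", cid, scenario))
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %d. %-17s ICER %10s  (%.0f DALYs averted, $%.0f)\n",
                  i, sub$intervention_id[i],
                  ifelse(is.finite(sub$icer[i]),
                         sprintf("%.0f", sub$icer[i]), "Inf"),
                  sub$dalys_averted[i], sub$incremental_cost[i]))
    }
  }
  invisible(d)
}

#' Command-line entry point
#'
#' In-process implementation of the shell interface (see
#' `inst/cli/anaemia-cea` for the Rscript wrapper). Subcommands:
#' `generate` (write a synthetic world's CSVs), `simulate` (run scenarios
#' and write targets/league/manifest) and `league` (print rankings from a
#' run directory).
#'
#' @param args Character vector of arguments, e.g.
#'   `c("simulate", "--synthetic", "20", "--seed", "7", "--out", "run1")`.
#' @return Integer exit code, invisibly (0 on success).
#' @export
cea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: anaemia-cea <generate|simulate|league> [options]",
    "  generate --synthetic N --seed S --out DIR",
    "  simulate [--countries CSV --interventions CSV | --synthetic N]",
    "           [--config YAML] [--scenario NAME|all] [--n-sims N]",
    "           [--seed S] [--group-by none|region|income] [--weighted]",
    "           --out DIR",
    "  league   --run DIR [--scenario NAME]", sep = "\n")
  if (length(args) < 1) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  code <- tryCatch({
    switch(cmd,
      generate = {
        n <- as.integer(opts[["synthetic"]] %||% 20)
        w <- generate_world(n, seed = as.integer(opts[["seed"]] %||% 1))
        write_world(w, opts[["out"]] %||% ".")
        0L
      },
      simulate = {
        cfg_args <- list()
        if (!is.null(opts[["config"]])) {
          cfg <- read_config(opts[["config"]])
          cfg_args <- unclass(cfg)[c("n_sims", "seed", "scenario",
                                     "daly_weights")]
        }
        if (!is.null(opts[["n-sims"]])) {
          cfg_args$n_sims <- as.integer(opts[["n-sims"]])
        }
        if (!is.null(opts[["seed"]])) {
          cfg_args$seed <- as.integer(opts[["seed"]])
        }
        sc <- opts[["scenario"]] %||% cfg_args$scenario %||% "cet_gdp1"
        if (!identical(sc, "all")) cfg_args$scenario <- sc
        config <- do.call(cea_config, cfg_args)
        world <- if (!is.null(opts[["synthetic"]])) {
          generate_world(as.integer(opts[["synthetic"]]),
                         seed = config$seed, config = config)
        } else NULL
        run_simulation(world, out_dir = opts[["out"]] %||% ".",
                       config = config, scenario = sc,
                       countries_path = opts[["countries"]],
                       interventions_path = opts[["interventions"]],
                       weighted = isTRUE(opts[["weighted"]]))
        0L
      },
      league = {
        league_report(opts[["run"]] %||% ".", scenario = opts[["scenario"]])
        0L
      },
      {
        message("unknown command: ", cmd, "\n", usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

# minimal --flag [value] parser; bare flags become TRUE
parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
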