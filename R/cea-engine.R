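# Core computation: intervention effects on the anaemic population, DALYs
# averted, incremental costs, ICERs, and the iterative greedy league-table
# loop. Burden is YLD-only (no anaemia-attributable mortality) over a 1-year
# horizon with no discounting; malaria-attributable YLDs are excluded.

#' Construct the mutable epidemiological state of one simulation
#'
#' Tracks the anaemic population by segment (non-pregnant, pregnant, and the
#' pregnant-with-malaria subset) as interventions are applied sequentially.
#' The severity split is held fixed as prevalence falls (cases resolve
#' proportionally across severities).
#'
#' @param profile A `country_profile`.
#' @param severity_split Optional override of the profile's severity split
#'   (used when the split is sampled).
#' @return A list of class `epi_state` with fields `anaemic_nonpregnant`,
#'   `anaemic_pregnant`, `anaemic_pregnant_malaria`, `severity_split`,
#'   `women_wra` and `initial_anaemic`.
#' @export
epi_state <- function(profile, severity_split = profile$severity_split) {
  structure(list(
    anaemic_nonpregnant = profile$anaemic_women - profile$pregnant_anaemic,
    anaemic_pregnant = profile$pregnant_anaemic,
    anaemic_pregnant_malaria = profile$pregnant_anaemic_malaria,
    severity_split = severity_split,
    women_wra = profile$women_wra,
    initial_anaemic = profile$anaemic_women
  ), class = "epi_state")
}

total_anaemic <- function(state) {
  state$anaemic_nonpregnant + state$anaemic_pregnant
}

#' Effectiveness at programmatic scale
#'
#' Trial efficacy of oral iron supplementation is discounted when rolled out
#' at scale: the risk reduction `1 - rr` is shrunk by the stated fraction,
#' i.e. the adjusted relative risk is `1 - (1 - rr) * (1 - reduction)`.
#' Composing on the risk-reduction scale keeps the adjusted RR at or below 1
#' whenever the trial RR is. Interventions not subject to the adjustment
#' (fortification, IPTp) pass through unchanged.
#'
#' @param rr Relative risk of remaining anaemic, in (0, 1.5].
#' @param reduction Proportional effectiveness reduction, in [0, 1).
#' @param apply Whether the adjustment applies to this intervention.
#' @return The effective relative risk (capped at 1 when adjusted).
#' @export
#' @examples
#' adjust_effectiveness(0.30, 0.38, TRUE)   # 0.566
#' adjust_effectiveness(0.73, 0.38, FALSE)  # 0.73 unchanged
adjust_effectiveness <- function(rr, reduction, apply) {
  if (!is_number(rr) || rr <= 0 || rr > 1.5) {
    stop_validation("rr must be in (0, 1.5]")
  }
  if (!is_number(reduction) || reduction < 0 || reduction >= 1) {
    stop_validation("reduction must be in [0, 1)")
  }
  if (!isTRUE(apply)) return(rr)
  min(1, 1 - (1 - rr) * (1 - reduction))
}

#' Coverage increment available to an intervention
#'
#' The scale-up reaches the gap between maximum and current coverage. In the
#' zero-baseline scenario current coverage is treated as nil, so the full
#' maximum acts on the baseline burden.
#'
#' @param spec An `intervention_spec` (or any list with `coverage_current`
#'   and `coverage_max`).
#' @param zero_baseline Logical; zero-baseline scenario flag.
#' @return The coverage increment, a fraction >= 0.
#' @export
delta_coverage <- function(spec, zero_baseline = FALSE) {
  if (isTRUE(zero_baseline)) return(spec$coverage_max)
  max(0, spec$coverage_max - spec$coverage_current)
}

receiving_pool <- function(profile, spec) {
  switch(spec$receiving_segment,
    total_population = profile$pop_total,
    all_wra_nonpregnant = profile$women_wra - profile$pregnant_women,
    pregnant = profile$pregnant_women,
    stop("unknown receiving segment: ", spec$receiving_segment))
}

benefitting_pool <- function(state, spec) {
  switch(spec$benefitting_segment,
    all_anaemic = total_anaemic(state),
    nonpregnant_anaemic = state$anaemic_nonpregnant,
    pregnant_anaemic = state$anaemic_pregnant,
    pregnant_anaemic_malaria = state$anaemic_pregnant_malaria,
    stop("unknown benefitting segment: ", spec$benefitting_segment))
}

#' Evaluate one intervention against the current state
#'
#' Computes the league-table entry of a single intervention versus status
#' quo at the current epidemiological state: cases averted are the
#' benefitting pool times the coverage increment times the risk reduction
#' `1 - rr`; DALYs (= YLDs) averted apply the severity-weighted mean
#' disability weight; incremental cost accrues over the receiving pool
#' (the whole population for fortification, since fortified staples reach
#' everyone); the ICER is cost per DALY averted, `+Inf` when no DALYs are
#' averted.
#'
#' @param state An `epi_state`.
#' @param profile The `country_profile` (fixed receiving pools).
#' @param spec An `intervention_spec`.
#' @param rr_effective Effective relative risk after any real-world
#'   adjustment.
#' @param delta_cov Coverage increment in [0, 1].
#' @param daly_weights Disability weights (mild, moderate, severe).
#' @return A list of class `league_entry` with `intervention_id`,
#'   `delta_coverage`, `rr_effective`, `cases_averted`, `dalys_averted`,
#'   `incremental_cost` and `icer`.
#' @export
evaluate_intervention <- function(state, profile, spec, rr_effective,
                                  delta_cov, daly_weights) {
  if (is.null(ELIGIBILITY_MAP[[spec$intervention_id]])) {
    stop("unknown intervention_id: ", spec$intervention_id)
  }
  if (delta_cov < 0 || delta_cov > 1) {
    stop_validation("delta_cov must be in [0,1]")
  }
  pool <- benefitting_pool(state, spec)
  cases <- pool * delta_cov * max(0, 1 - rr_effective)
  w_mean <- sum(state$severity_split * daly_weights)
  dalys <- cases * w_mean
  cost <- receiving_pool(profile, spec) * delta_cov * spec$unit_cost
  icer <- if (dalys > 0) cost / dalys else Inf
  structure(list(
    intervention_id = spec$intervention_id,
    delta_coverage = delta_cov,
    rr_effective = rr_effective,
    cases_averted = cases,
    dalys_averted = dalys,
    incremental_cost = cost,
    icer = icer
  ), class = "league_entry")
}

#' Apply an intervention to the state
#'
#' The benefitting segment's anaemic count is multiplied by
#' `1 - delta_cov * (1 - rr_effective)`. Nested counts stay consistent:
#' reducing pregnant anaemia reduces its malaria subset proportionally,
#' while IPTp removes cases from the malaria subset and decrements the
#' pregnant anaemic count by the same absolute amount. The severity split is
#' unchanged.
#'
#' @inheritParams evaluate_intervention
#' @return The updated `epi_state`.
#' @export
apply_intervention <- function(state, spec, rr_effective, delta_cov) {
  f <- 1 - delta_cov * max(0, 1 - rr_effective)   # residual fraction
  s <- state
  switch(spec$benefitting_segment,
    all_anaemic = {
      s$anaemic_nonpregnant <- s$anaemic_nonpregnant * f
      s$anaemic_pregnant <- s$anaemic_pregnant * f
      s$anaemic_pregnant_malaria <- s$anaemic_pregnant_malaria * f
    },
    nonpregnant_anaemic = {
      s$anaemic_nonpregnant <- s$anaemic_nonpregnant * f
    },
    pregnant_anaemic = {
      s$anaemic_pregnant <- s$anaemic_pregnant * f
      s$anaemic_pregnant_malaria <- s$anaemic_pregnant_malaria * f
    },
    pregnant_anaemic_malaria = {
      averted <- s$anaemic_pregnant_malaria * (1 - f)
      s$anaemic_pregnant_malaria <- s$anaemic_pregnant_malaria - averted
      s$anaemic_pregnant <- s$anaemic_pregnant - averted
    },
    stop("unknown benefitting segment: ", spec$benefitting_segment))
  stopifnot(s$anaemic_nonpregnant >= 0, s$anaemic_pregnant >= -1e-9,
            s$anaemic_pregnant_malaria <= s$anaemic_pregnant + 1e-9)
  s
}

#' Build a league table at the current state
#'
#' Evaluates every candidate intervention against the current state and
#' orders entries by increasing ICER; ties are broken by greater DALYs
#' averted, then lexicographic intervention id.
#'
#' @param state An `epi_state`.
#' @param profile The `country_profile`.
#' @param specs Named list of `intervention_spec` candidates.
#' @param params A sampled-parameter set from [sample_params()] (or
#'   [point_params()] for a deterministic run).
#' @param config A `cea_config`.
#' @param zero_baseline Zero-baseline coverage rule flag.
#' @return List of `league_entry`, sorted.
#' @export
build_league_table <- function(state, profile, specs, params, config,
                               zero_baseline = FALSE) {
  stopifnot(length(specs) > 0)
  entries <- lapply(specs, function(sp) {
    id <- sp$intervention_id
    rr_eff <- adjust_effectiveness(params$rr[[id]],
                                   params$real_world_reduction,
                                   sp$real_world_adjust)
    dc <- delta_coverage(list(coverage_current = params$coverage_current[[id]],
                              coverage_max = params$coverage_max[[id]]),
                         zero_baseline)
    sp$unit_cost <- params$unit_cost[[id]]
    evaluate_intervention(state, profile, sp, rr_eff, dc,
                          config$daly_weights)
  })
  ord <- order(vapply(entries, `[[`, 0, "icer"),
               -vapply(entries, `[[`, 0, "dalys_averted"),
               vapply(entries, `[[`, "", "intervention_id"))
  unname(entries[ord])
}

#' Iterative cost-effectiveness-ranked application of interventions
#'
#' The country-level decision loop: build a league table on the current
#' state; if the lowest ICER is strictly below the country's
#' cost-effectiveness threshold, apply that intervention at its full
#' coverage increment, remove it from the candidate set, and repeat (ICERs
#' of the remaining interventions are recomputed on the shrunken anaemic
#' population). The loop stops when every intervention is applied or none of
#' the rest is cost-effective; the resulting prevalence is the maximum
#' cost-effective improvement. With an infinite threshold (no-constraint
#' scenario) every intervention with positive coverage headroom is applied.
#'
#' @param profile A `country_profile`.
#' @param specs Named list of the four `intervention_spec` objects.
#' @param params Sampled (or point) parameter set.
#' @param cet Willingness-to-pay threshold in USD per DALY averted, or
#'   `Inf`.
#' @param config A `cea_config`.
#' @param zero_baseline Zero-baseline coverage rule flag.
#' @return A list of class `country_run` with `applied_sequence`,
#'   `initial_anaemic`, `final_anaemic`, `relative_reduction_pct`,
#'   `final_state` and `league_history` (one sorted table per iteration).
#' @export
greedy_apply <- function(profile, specs, params, cet, config,
                         zero_baseline = FALSE) {
  if (!(is_number(cet) && cet >= 0) && !identical(cet, Inf)) {
    stop_validation("cet must be a non-negative number or Inf")
  }
  state <- epi_state(profile, params$severity_split %||%
                       profile$severity_split)
  candidates <- specs
  applied <- character(0)
  history <- list()
  prev_icer <- numeric(0)
  while (length(candidates) > 0) {
    table <- build_league_table(state, profile, candidates, params, config,
                                zero_baseline)
    history[[length(history) + 1L]] <- table
    # ICERs of still-unapplied interventions can only rise as the pools shrink
    for (e in table) {
      old <- prev_icer[e$intervention_id]
      if (!is.na(old) && is.finite(old)) {
        stopifnot(is.infinite(e$icer) ||
                    e$icer >= old - 1e-6 * max(1, abs(old)))
      }
      prev_icer[e$intervention_id] <- e$icer
    }
    best <- table[[1]]
    take <- if (is.infinite(cet)) {
      best$delta_coverage > 0
    } else {
      best$icer < cet
    }
    if (!take) break
    sp <- candidates[[best$intervention_id]]
    state <- apply_intervention(state, sp, best$rr_effective,
                                best$delta_coverage)
    applied <- c(applied, best$intervention_id)
    candidates[[best$intervention_id]] <- NULL
  }
  init <- state$initial_anaemic
  fin <- total_anaemic(state)
  structure(list(
    applied_sequence = applied,
    initial_anaemic = init,
    final_anaemic = fin,
    relative_reduction_pct = relative_reduction(init, fin),
    final_state = state,
    league_history = history
  ), class = "country_run")
}

#' Relative reduction in burden, percent
#'
#' Percentage fall from an initial to a final burden (counts or prevalence,
#' any consistent unit). A country with 4% prevalence that reaches 3%
#' achieves a 25% relative reduction. Zero initial burden is defined as a 0%
#' reduction (there is nothing to reduce).
#'
#' @param p_initial Initial burden, >= 0.
#' @param p_final Final burden, in [0, p_initial].
#' @return `(p_initial - p_final) / p_initial * 100`.
#' @export
#' @examples
#' relative_reduction(4, 3)  # 25
relative_reduction <- function(p_initial, p_final) {
  if (!is_number(p_initial) || p_initial < 0) {
    stop_validation("p_initial must be a non-negative number")
  }
  if (p_initial == 0) return(0)
  if (!is_number(p_final) || p_final < 0 || p_final > p_initial * (1 + 1e-12)) {
    stop_validation("p_final must lie in [0, p_initial]")
  }
  (p_initial - p_final) / p_initial * 100
}

#' @export
print.country_run <- function(x, ...) {
  cat("<country_run>\n")
  cat("  applied:", if (length(x$applied_sequence)) {
    paste(x$applied_sequence, collapse = " -> ")
  } else "(none)", "\n")
  cat(sprintf("  anaemic: %.0f -> %.0f  (%.1f%% relative reduction)\n",
              x$initial_anaemic, x$final_anaemic, x$relative_reduction_pct))
  invisible(x)
}
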