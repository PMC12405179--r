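# Shared fixtures and an independent brute-force oracle for the decision
# loop. The oracle re-derives pools, ICERs and state updates with plain
# arithmetic and never calls the engine's functions.

make_profile <- function(pop_total = 4e6, women_wra = 1e6,
                         anaemic = 3e5, pregnant = 8e4,
                         pregnant_anaemic = 3e4, malaria = 6e3,
                         severity = c(0.6, 0.35, 0.05),
                         gdp = 2000, cet_opp = 750, id = "TST") {
  country_profile(id, paste0("Test-", id), "Test region", "Test income",
                  pop_total = pop_total, women_wra = women_wra,
                  anaemic_women = anaemic, pregnant_women = pregnant,
                  pregnant_anaemic = pregnant_anaemic,
                  pregnant_anaemic_malaria = malaria,
                  severity_split = severity, gdp_per_capita = gdp,
                  cet_opportunity = cet_opp)
}

make_specs <- function(cov_cur = c(0.2, 0.1, 0.4, 0.1),
                       cov_max = c(0.8, 0.7, 0.9, 0.6),
                       cost = c(0.25, 5, 8, 2)) {
  specs <- default_interventions()
  for (i in seq_along(specs)) {
    specs[[i]]$coverage_current <- cov_cur[i]
    specs[[i]]$coverage_max <- cov_max[i]
    specs[[i]]$unit_cost <- cost[i]
  }
  specs
}

# a randomized, always-valid country instance at point parameters
random_instance <- function(seed) {
  set.seed(seed)
  wra <- runif(1, 1e5, 5e6)
  anaemic <- wra * runif(1, 0.05, 0.6)
  pregnant <- wra * runif(1, 0.02, 0.18)
  preg_an <- min(anaemic, pregnant) * runif(1, 0.1, 1)
  malaria <- preg_an * runif(1, 0, 0.6)
  sev <- as.numeric(rmultinom(1, 1000, c(0.6, 0.35, 0.05))) / 1000
  profile <- make_profile(pop_total = wra * runif(1, 3, 5), women_wra = wra,
                          anaemic = anaemic, pregnant = pregnant,
                          pregnant_anaemic = preg_an, malaria = malaria,
                          severity = sev, gdp = exp(runif(1, log(500),
                                                          log(5e4))),
                          cet_opp = exp(runif(1, log(100), log(2e4))),
                          id = paste0("R", seed))
  specs <- make_specs(cov_cur = runif(4, 0, 0.7),
                      cov_max = runif(4, 0.3, 1),
                      cost = c(runif(1, 0.05, 2), runif(2, 1, 20),
                               runif(1, 0.5, 8)))
  # randomize effectiveness too, keeping CI invariants
  for (id in names(specs)) {
    med <- runif(1, 0.2, 0.95)
    specs[[id]]$rr_median <- med
    specs[[id]]$rr_ci_low <- med * runif(1, 0.6, 1)
    specs[[id]]$rr_ci_high <- min(1.4, med / runif(1, 0.6, 1))
    validate_intervention(specs[[id]])
  }
  cfg <- cea_config(n_sims = 2, seed = seed)
  list(profile = profile, specs = specs, config = cfg,
       params = point_params(specs, cfg, sev))
}

# Brute-force simulation of the decision loop: at each step recompute every
# remaining intervention's cases/DALYs/cost/ICER from first principles, pick
# the cheapest per DALY (ties: more DALYs, then id), apply it if its ICER is
# strictly below the threshold, repeat.
oracle_greedy <- function(profile, specs, params, cet, weights,
                          zero_baseline = FALSE) {
  np <- profile$anaemic_women - profile$pregnant_anaemic
  pr <- profile$pregnant_anaemic
  pm <- profile$pregnant_anaemic_malaria
  init <- profile$anaemic_women
  wbar <- sum(params$severity_split * weights)
  remaining <- names(specs)
  applied <- character(0)
  eval_one <- function(id) {
    s <- specs[[id]]
    rr <- params$rr[[id]]
    if (s$real_world_adjust) {
      rr <- min(1, 1 - (1 - rr) * (1 - params$real_world_reduction))
    }
    dc <- if (zero_baseline) params$coverage_max[[id]] else {
      max(0, params$coverage_max[[id]] - params$coverage_current[[id]])
    }
    pool <- switch(id, fortification = np + pr, iron_nonpregnant = np,
                   iron_pregnant = pr, iptp = pm)
    recv <- switch(id, fortification = profile$pop_total,
                   iron_nonpregnant = profile$women_wra - profile$pregnant_women,
                   iron_pregnant = profile$pregnant_women,
                   iptp = profile$pregnant_women)
    cases <- pool * dc * max(0, 1 - rr)
    dalys <- cases * wbar
    cost <- recv * dc * params$unit_cost[[id]]
    list(id = id, rr = rr, dc = dc, cases = cases, dalys = dalys,
         icer = if (dalys > 0) cost / dalys else Inf)
  }
  repeat {
    if (length(remaining) == 0) break
    evals <- lapply(remaining, eval_one)
    icers <- vapply(evals, `[[`, 0, "icer")
    dalys <- vapply(evals, `[[`, 0, "dalys")
    ord <- order(icers, -dalys, remaining)
    best <- evals[[ord[1]]]
    take <- if (is.infinite(cet)) best$dc > 0 else best$icer < cet
    if (!take) break
    g <- best$dc * max(0, 1 - best$rr)
    switch(best$id,
      fortification = { np <- np * (1 - g); pr <- pr * (1 - g)
                        pm <- pm * (1 - g) },
      iron_nonpregnant = { np <- np * (1 - g) },
      iron_pregnant = { pr <- pr * (1 - g); pm <- pm * (1 - g) },
      iptp = { x <- pm * g; pm <- pm - x; pr <- pr - x })
    applied <- c(applied, best$id)
    remaining <- setdiff(remaining, best$id)
  }
  list(applied = applied, final = np + pr,
       reduction_pct = if (init > 0) (init - (np + pr)) / init * 100 else 0)
}
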