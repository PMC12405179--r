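cfg <- cea_config(n_sims = 2, seed = 1)

test_that("real-world adjustment shrinks the risk reduction, not the RR", {
  expect_equal(adjust_effectiveness(0.30, 0.38, TRUE), 0.566)
  expect_equal(adjust_effectiveness(0.30, 0.38, FALSE), 0.30)
  expect_equal(adjust_effectiveness(1.0, 0.38, TRUE), 1.0)
  # RR > 1 (harmful draw) is capped at 1 after adjustment
  expect_equal(adjust_effectiveness(1.2, 0.38, TRUE), 1.0)
  expect_error(adjust_effectiveness(0.3, 1.0, TRUE),
               class = "cea_validation_error")
})

test_that("coverage increment is the clamped headroom, or the max at zero baseline", {
  s <- list(coverage_current = 0.3, coverage_max = 0.8)
  expect_equal(delta_coverage(s), 0.5)
  expect_equal(delta_coverage(list(coverage_current = 0.9,
                                   coverage_max = 0.8)), 0)
  expect_equal(delta_coverage(s, zero_baseline = TRUE), 0.8)
})

test_that("league entry arithmetic matches the hand-computed example", {
  profile <- make_profile()   # 300k anaemic, 30k pregnant, pop 4M
  state <- epi_state(profile)
  spec <- default_interventions()$fortification
  spec$unit_cost <- 0.25
  # flat 0.05 weight so the severity-weighted mean is exactly 0.05
  e <- evaluate_intervention(state, profile, spec, rr_effective = 0.73,
                             delta_cov = 0.5,
                             daly_weights = c(0.05, 0.05, 0.05))
  expect_equal(e$cases_averted, 40500)
  expect_equal(e$dalys_averted, 2025)
  expect_equal(e$incremental_cost, 500000)
  expect_equal(e$icer, 500000 / 2025)  # ~246.91

  # null effect and no scale-up both produce an infinite ICER
  e0 <- evaluate_intervention(state, profile, spec, 1.0, 0.5,
                              cfg$daly_weights)
  expect_equal(e0$cases_averted, 0)
  expect_equal(e0$icer, Inf)
  e1 <- evaluate_intervention(state, profile, spec, 0.73, 0,
                              cfg$daly_weights)
  expect_equal(e1$dalys_averted, 0)
  expect_equal(e1$icer, Inf)
})

test_that("applying an intervention updates nested segments consistently", {
  profile <- make_profile()
  state <- epi_state(profile)
  specs <- default_interventions()
  # fortification removes the example's 40500 cases across all segments
  s2 <- apply_intervention(state, specs$fortification, 0.73, 0.5)
  expect_equal(s2$anaemic_nonpregnant + s2$anaemic_pregnant, 259500)
  # proportional: pregnant share unchanged
  expect_equal(s2$anaemic_pregnant / (s2$anaemic_pregnant +
                                        s2$anaemic_nonpregnant),
               30000 / 300000)
  # zero delta-coverage is the identity
  s3 <- apply_intervention(state, specs$iron_pregnant, 0.3, 0)
  expect_equal(s3, state)
  # iptp decrements malaria subset and pregnant count by the same amount
  s4 <- apply_intervention(state, specs$iptp, 0.9, 0.5)
  averted <- 6000 * 0.5 * 0.1
  expect_equal(s4$anaemic_pregnant_malaria, 6000 - averted)
  expect_equal(s4$anaemic_pregnant, 30000 - averted)
  expect_equal(s4$anaemic_nonpregnant, state$anaemic_nonpregnant)
  # pregnant-iron shrinks the malaria subset proportionally
  s5 <- apply_intervention(state, specs$iron_pregnant, 0.5, 0.4)
  expect_equal(s5$anaemic_pregnant, 30000 * 0.8)
  expect_equal(s5$anaemic_pregnant_malaria, 6000 * 0.8)
})

test_that("league table sorts by ICER with DALY and id tie-breaks", {
  inst <- random_instance(77)
  state <- epi_state(inst$profile)
  tab <- build_league_table(state, inst$profile, inst$specs, inst$params,
                            inst$config)
  icers <- vapply(tab, `[[`, 0, "icer")
  expect_true(all(diff(icers) >= 0))
  # engineered tie: two interventions with equal ICER, different DALYs
  profile <- make_profile()
  specs <- make_specs(cov_cur = c(0, 0, 0, 0), cov_max = c(0.5, 0, 0.5, 0))
  # choose costs so fortification and iron_pregnant have identical ICERs
  params <- point_params(specs, cfg, profile$severity_split)
  params$rr <- c(fortification = 0.5, iron_nonpregnant = 0.5,
                 iron_pregnant = 0.5, iptp = 0.5)
  params$real_world_reduction <- 0
  w <- sum(profile$severity_split * cfg$daly_weights)
  # icer = recv*cost/(pool*0.5*w): equalise via costs
  params$unit_cost <- c(
    fortification = 1,
    iron_nonpregnant = 1,
    iron_pregnant = (profile$pop_total * 1 / (3e5 * 0.5 * w)) *
      (3e4 * 0.5 * w) / profile$pregnant_women,
    iptp = 1)
  state <- epi_state(profile)
  tab <- build_league_table(state, profile, specs, params, cfg)
  expect_equal(tab[[1]]$icer, tab[[2]]$icer, tolerance = 1e-12)
  expect_gte(tab[[1]]$dalys_averted, tab[[2]]$dalys_averted)
  # all-zero headroom: every ICER infinite
  specs0 <- make_specs(cov_cur = c(0.5, 0.5, 0.5, 0.5),
                       cov_max = c(0.5, 0.5, 0.5, 0.5))
  tab0 <- build_league_table(state, profile, specs0,
                             point_params(specs0, cfg), cfg)
  expect_true(all(vapply(tab0, `[[`, 0, "icer") == Inf))
})

test_that("greedy loop honours the threshold gate", {
  inst <- random_instance(5)
  # cet = 0: nothing is cost-effective (strict inequality)
  r0 <- greedy_apply(inst$profile, inst$specs, inst$params, 0, inst$config)
  expect_length(r0$applied_sequence, 0)
  expect_equal(r0$relative_reduction_pct, 0)
  # cet = Inf: every intervention with positive headroom applied
  rInf <- greedy_apply(inst$profile, inst$specs, inst$params, Inf,
                       inst$config)
  pos <- vapply(inst$specs, function(s) delta_coverage(s) > 0, NA)
  expect_setequal(rInf$applied_sequence, names(inst$specs)[pos])
  # reduction consistent with counts
  expect_equal(rInf$relative_reduction_pct,
               (rInf$initial_anaemic - rInf$final_anaemic) /
                 rInf$initial_anaemic * 100)
})

test_that("greedy loop matches the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    for (cet in c(0, 200, 2000, 2e4, Inf)) {
      got <- greedy_apply(inst$profile, inst$specs, inst$params, cet,
                          inst$config)
      want <- oracle_greedy(inst$profile, inst$specs, inst$params, cet,
                            inst$config$daly_weights)
      expect_identical(got$applied_sequence, want$applied,
                       info = paste("seed", seed, "cet", cet))
      expect_equal(got$final_anaemic, want$final, tolerance = 1e-12)
    }
  }
})

test_that("unconstrained application equals the order-independent closed form", {
  for (seed in 101:140) {
    inst <- random_instance(seed)
    params <- inst$params
    r <- greedy_apply(inst$profile, inst$specs, params, Inf, inst$config)
    f <- function(id) {
      s <- inst$specs[[id]]
      rr <- adjust_effectiveness(params$rr[[id]],
                                 params$real_world_reduction,
                                 s$real_world_adjust)
      1 - delta_coverage(s) * max(0, 1 - rr)
    }
    np0 <- inst$profile$anaemic_women - inst$profile$pregnant_anaemic
    p0 <- inst$profile$pregnant_anaemic
    pm0 <- inst$profile$pregnant_anaemic_malaria
    np_f <- np0 * f("fortification") * f("iron_nonpregnant")
    p_f <- f("fortification") * f("iron_pregnant") *
      (p0 - pm0 * (1 - f("iptp")))
    expect_equal(r$final_anaemic, np_f + p_f, tolerance = 1e-9)
  }
})

test_that("single-intervention reduction follows the closed form", {
  for (seed in 201:240) {
    inst <- random_instance(seed)
    id <- sample(names(inst$specs), 1)
    specs1 <- inst$specs[id]
    r <- greedy_apply(inst$profile, specs1, inst$params, Inf, inst$config)
    s <- specs1[[1]]
    rr <- adjust_effectiveness(inst$params$rr[[id]],
                               inst$params$real_world_reduction,
                               s$real_world_adjust)
    pool <- switch(id,
      fortification = inst$profile$anaemic_women,
      iron_nonpregnant = inst$profile$anaemic_women -
        inst$profile$pregnant_anaemic,
      iron_pregnant = inst$profile$pregnant_anaemic,
      iptp = inst$profile$pregnant_anaemic_malaria)
    want <- pool / inst$profile$anaemic_women * delta_coverage(s) *
      max(0, 1 - rr) * 100
    expect_equal(r$relative_reduction_pct, want, tolerance = 1e-9)
  }
})

test_that("burden is monotone non-increasing across iterations", {
  for (seed in 301:330) {
    inst <- random_instance(seed)
    r <- greedy_apply(inst$profile, inst$specs, inst$params,
                      inst$profile$gdp_per_capita, inst$config)
    expect_lte(r$final_anaemic, r$initial_anaemic + 1e-9 * r$initial_anaemic)
    # replay the applied sequence and check the running total
    state <- epi_state(inst$profile)
    tot <- state$anaemic_nonpregnant + state$anaemic_pregnant
    for (k in seq_along(r$applied_sequence)) {
      e <- r$league_history[[k]][[1]]
      state <- apply_intervention(state, inst$specs[[e$intervention_id]],
                                  e$rr_effective, e$delta_coverage)
      new_tot <- state$anaemic_nonpregnant + state$anaemic_pregnant
      expect_lte(new_tot, tot + 1e-9)
      tot <- new_tot
    }
  }
})

test_that("relative reduction handles the documented edge cases", {
  expect_equal(relative_reduction(4, 3), 25)
  expect_equal(relative_reduction(7.3, 7.3), 0)
  expect_equal(relative_reduction(12, 0), 100)
  expect_equal(relative_reduction(0, 0), 0)
  expect_error(relative_reduction(3, 4), class = "cea_validation_error")
})
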