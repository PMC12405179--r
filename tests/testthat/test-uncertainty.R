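cfg <- cea_config(n_sims = 10, seed = 42)

test_that("RR draws reproduce the published median and CI endpoints", {
  specs <- default_interventions()
  set.seed(1)
  draws <- vapply(1:10000, function(i) {
    sample_params(specs, cfg)$rr[["iron_pregnant"]]
  }, 0)
  expect_lt(abs(median(draws) - 0.30), 0.01)
  q <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(q[1] - 0.20), 0.02)
  expect_lt(abs(q[2] - 0.47), 0.02)
})

test_that("coverage draws collapse to the point estimate as concentration grows", {
  specs <- make_specs()
  cfg_inf <- cea_config(coverage_concentration = Inf, cost_cv = 0,
                        severity_concentration = 1e9)
  set.seed(2)
  p <- sample_params(specs, cfg_inf)
  expect_equal(unname(p$coverage_current),
               vapply(specs, `[[`, 0, "coverage_current"),
               ignore_attr = TRUE)
  expect_equal(unname(p$unit_cost), vapply(specs, `[[`, 0, "unit_cost"),
               ignore_attr = TRUE)
  # large finite concentration: draws close to the point estimate
  cfg_big <- cea_config(coverage_concentration = 1e6)
  set.seed(3)
  p2 <- sample_params(specs, cfg_big)
  expect_equal(unname(p2$coverage_current),
               vapply(specs, `[[`, 0, "coverage_current"),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("a degenerate CI is treated as a point mass", {
  specs <- default_interventions()
  specs$iptp$rr_ci_low <- specs$iptp$rr_ci_high <- specs$iptp$rr_median
  set.seed(4)
  p <- sample_params(specs, cfg)
  expect_equal(p$rr[["iptp"]], specs$iptp$rr_median)
})

test_that("sampled parameter sets respect their domains and are reproducible", {
  specs <- make_specs()
  for (i in 1:200) {
    set.seed(i)
    p <- sample_params(specs, cfg, c(0.6, 0.35, 0.05))
    expect_true(all(p$rr > 0 & p$rr <= 1.5))
    expect_true(p$real_world_reduction >= 0 && p$real_world_reduction < 1)
    expect_true(all(p$coverage_current >= 0 & p$coverage_current <= 1))
    expect_true(all(p$coverage_max >= 0 & p$coverage_max <= 1))
    expect_true(all(p$unit_cost >= 0))
    expect_equal(sum(p$severity_split), 1)
  }
  set.seed(7); a <- sample_params(specs, cfg)
  set.seed(7); b <- sample_params(specs, cfg)
  expect_identical(a, b)
})

test_that("scenario resolution maps to the documented thresholds", {
  p <- make_profile(gdp = 2000, cet_opp = 750)
  expect_equal(cet_for_scenario(p, "cet_gdp1"), 2000)
  expect_equal(cet_for_scenario(p, "cet_opportunity"), 750)
  expect_equal(cet_for_scenario(p, "no_constraint"), Inf)
  expect_equal(cet_for_scenario(p, "zero_baseline"), 2000)
  expect_error(cet_for_scenario(p, "bogus"), "unknown scenario")
})

test_that("country Monte Carlo is deterministic, bounded, and null under RR = 1", {
  inst <- random_instance(9)
  cfg50 <- cea_config(n_sims = 50, seed = 5)
  sims <- run_country_mc(inst$profile, inst$specs, cfg50)
  expect_length(sims, 50)
  expect_true(all(sims >= 0 & sims <= 100))
  expect_identical(sims, run_country_mc(inst$profile, inst$specs, cfg50))
  # forcing every RR to 1 (degenerate CI at 1) removes all effect
  specs1 <- inst$specs
  for (id in names(specs1)) {
    specs1[[id]]$rr_median <- 1
    specs1[[id]]$rr_ci_low <- 1
    specs1[[id]]$rr_ci_high <- 1
  }
  # the real-world adjustment cannot resurrect a null effect
  expect_true(all(run_country_mc(inst$profile, specs1, cfg50) == 0))
})

test_that("point-mass sampling reproduces the deterministic run", {
  inst <- random_instance(21)
  specs <- inst$specs
  for (id in names(specs)) {   # degenerate CIs
    specs[[id]]$rr_ci_low <- specs[[id]]$rr_ci_high <- specs[[id]]$rr_median
  }
  cfgp <- cea_config(n_sims = 20, seed = 3,
                     coverage_concentration = Inf, cost_cv = 0,
                     severity_concentration = Inf,
                     effectiveness_reduction_median = 0.38,
                     effectiveness_reduction_ci = c(0.38, 0.38))
  sims <- run_country_mc(inst$profile, specs, cfgp)
  det <- greedy_apply(inst$profile, specs,
                      point_params(specs, cfgp, inst$profile$severity_split),
                      cet_for_scenario(inst$profile, "cet_gdp1"), cfgp)
  expect_equal(sims, rep(det$relative_reduction_pct, 20), tolerance = 1e-12)
})
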