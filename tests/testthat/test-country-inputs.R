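test_that("country CSV round-trips field-for-field and preserves order", {
  p1 <- make_profile(id = "AAA")
  p2 <- make_profile(id = "BBB", anaemic = 2e5, pregnant_anaemic = 2e4,
                     malaria = 1e3, gdp = 30000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_countries(list(p1, p2), path)
  back <- read_countries(path)
  expect_length(back, 2)
  expect_identical(vapply(back, `[[`, "", "country_id"), c("AAA", "BBB"))
  for (f in setdiff(names(p1), "severity_split")) {
    expect_equal(back[[1]][[f]], p1[[f]], info = f)
  }
  expect_equal(back[[1]]$severity_split, p1$severity_split)
  # writing what was read reproduces the file byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_countries(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("validation errors name the offending country and field", {
  expect_error(make_profile(anaemic = 2e6),   # exceeds women_wra
               "TST.*anaemic_women", class = "cea_validation_error")
  expect_error(make_profile(malaria = 5e4),
               "pregnant_anaemic_malaria", class = "cea_validation_error")
  expect_error(make_profile(severity = c(0.5, 0.3, 0.3)),
               "severity_split", class = "cea_validation_error")
  expect_error(make_profile(gdp = 0), "gdp_per_capita",
               class = "cea_validation_error")
  # boundary severity split accepted
  expect_s3_class(make_profile(severity = c(0.5, 0.3, 0.2)),
                  "country_profile")
  # a bad row inside a file is reported with its country id
  p <- make_profile(id = "BAD")
  path <- withr::local_tempfile(fileext = ".csv")
  write_countries(list(p), path)
  df <- read.csv(path)
  df$anaemic_women <- df$women_wra * 2
  write.csv(df, path, row.names = FALSE)
  expect_error(read_countries(path), "BAD")
})

test_that("missing columns give a schema error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_countries(list(make_profile()), path)
  df <- read.csv(path)
  df$gdp_per_capita <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_countries(path), "gdp_per_capita")
})

test_that("non-pregnant iron coverage is a clamped fraction of pregnant coverage", {
  expect_equal(derive_nonpregnant_iron_coverage(0.60, 0.41), 0.246)
  expect_equal(derive_nonpregnant_iron_coverage(0.0, 0.41), 0)
  expect_equal(derive_nonpregnant_iron_coverage(1.0, 1.0), 1)
  expect_error(derive_nonpregnant_iron_coverage(1.2, 0.41),
               class = "cea_validation_error")
})

test_that("default interventions carry the published effectiveness estimates", {
  specs <- default_interventions()
  expect_setequal(names(specs), c("fortification", "iron_nonpregnant",
                                  "iron_pregnant", "iptp"))
  ip <- specs$iron_pregnant
  expect_equal(ip$rr_median, 0.30)
  expect_equal(c(ip$rr_ci_low, ip$rr_ci_high), c(0.20, 0.47))
  expect_equal(specs$fortification$rr_median, 0.73)
  expect_equal(specs$iptp$rr_median, 0.90)
  expect_equal(specs$iron_nonpregnant$rr_median, 0.65)
  # real-world adjustment only for the oral-iron interventions
  expect_false(specs$fortification$real_world_adjust)
  expect_false(specs$iptp$real_world_adjust)
  expect_true(specs$iron_pregnant$real_world_adjust)
  expect_true(specs$iron_nonpregnant$real_world_adjust)
})

test_that("eligibility mapping is fixed per intervention", {
  specs <- default_interventions()
  expect_equal(specs$fortification$receiving_segment, "total_population")
  expect_equal(specs$fortification$benefitting_segment, "all_anaemic")
  expect_equal(specs$iron_nonpregnant$receiving_segment,
               "all_wra_nonpregnant")
  expect_equal(specs$iptp$benefitting_segment, "pregnant_anaemic_malaria")
  bad <- specs$iptp
  bad$benefitting_segment <- "all_anaemic"
  expect_error(validate_intervention(bad), "eligibility")
})

test_that("intervention CSV supports per-country overrides", {
  specs <- make_specs()
  by_country <- list(AAA = specs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interventions(by_country, path)
  tabs <- read_interventions(path)
  resolved <- specs_for_country(tabs, "AAA")
  expect_equal(resolved$fortification$unit_cost,
               specs$fortification$unit_cost)
  # defaults + one override
  specs2 <- specs
  specs2$iptp$unit_cost <- 99
  write_interventions(specs, path)  # global defaults, no country_id
  df <- read.csv(path)
  ov <- df[df$intervention_id == "iptp", ]
  ov$unit_cost <- 99
  ov$country_id <- "BBB"
  write.csv(rbind(df, ov), path, row.names = FALSE)
  tabs <- read_interventions(path)
  expect_equal(specs_for_country(tabs, "BBB")$iptp$unit_cost, 99)
  expect_equal(specs_for_country(tabs, "CCC")$iptp$unit_cost,
               specs$iptp$unit_cost)
})

test_that("config validates disability weights and reduction CI", {
  expect_error(cea_config(daly_weights = c(0.05, 0.05, 0.1)),
               "daly_weights", class = "cea_validation_error")
  expect_error(cea_config(effectiveness_reduction_median = 1.2),
               class = "cea_validation_error")
  cfg <- cea_config()
  expect_equal(cfg$daly_weights, c(0.004, 0.052, 0.149))
  expect_equal(cfg$effectiveness_reduction_median, 0.38)
  expect_equal(cfg$effectiveness_reduction_ci, c(0.21, 0.69))
  expect_equal(cfg$nonpregnant_coverage_fraction, 0.41)
  expect_equal(cfg$n_sims, 1000L)
})

test_that("YAML config round-trips through read_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_sims: 77", "seed: 5", "scenario: no_constraint",
               "cost_cv: 0.1"), path)
  cfg <- read_config(path)
  expect_equal(cfg$n_sims, 77L)
  expect_equal(cfg$scenario, "no_constraint")
  expect_equal(cfg$cost_cv, 0.1)
  expect_warning(
    {
      writeLines(c("n_sims: 5", "bogus_key: 1"), path)
      read_config(path)
    }, "bogus_key")
})
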