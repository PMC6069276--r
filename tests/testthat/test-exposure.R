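test_that("population-equivalent water concentrations are coverage-weighted means", {
  expect_equal(equivalent_water_concentration(0.70, 0.7, 0.05), 0.505)
  expect_equal(round(equivalent_water_concentration(0.70, 0.7, 0.05), 1), 0.5)
  expect_equal(equivalent_water_concentration(1.0, 0.9, 0.3), 0.9)
  # 2.5% coverage: 0.025*0.7 + 0.975*0.05
  expect_equal(equivalent_water_concentration(0.025, 0.7, 0.05), 0.06625)
  expect_error(equivalent_water_concentration(1.2, 0.7, 0.05),
               class = "fluopbpk_domain_error")
})

test_that("absorbed intakes apply the per-medium bioavailability", {
  bw <- 16
  expect_equal(absorbed_intake(exposure_source("toothpaste", 40), bw), 40)
  expect_equal(absorbed_intake(exposure_source("diet", 21), bw), 8.4)
  water <- exposure_source("water", volume_L_day = 0.442,
                           concentration_mg_L = 0.7)
  expect_equal(absorbed_intake(water, bw), 0.442 * 700 / 16 * 0.83)
  expect_equal(absorbed_intake(water, bw), 16.05, tolerance = 1e-3)
  no_conc <- exposure_source("water", volume_L_day = 0.442)
  expect_error(absorbed_intake(no_conc, bw), "concentration",
               class = "fluopbpk_config_error")
  # absorbed never exceeds ingested
  for (m in c("diet", "toothpaste", "soil", "air")) {
    expect_lte(absorbed_intake(exposure_source(m, 10), bw), 10)
  }
})

test_that("total absorbed TDFI reproduces the per-source arithmetic", {
  scn <- scenario_preset("fluoridated-tap", 4)
  expect_equal(total_absorbed_tdfi(scn), 64.9, tolerance = 1e-3)
  expect_equal(scenario_daily_dose(scn), 64.94 * 16 / 1000, tolerance = 1e-3)
  # linearity: doubling every intake doubles the total
  doubled <- scn
  doubled$sources <- lapply(scn$sources, function(s) {
    if (s$medium == "water") s$volume_L_day <- s$volume_L_day * 2
    else s$intake_ugkgday <- s$intake_ugkgday * 2
    s
  })
  expect_equal(total_absorbed_tdfi(doubled), 2 * total_absorbed_tdfi(scn))
})

test_that("source contributions are normalized shares, invariant to uniform scaling", {
  scn <- scenario_preset("fluoridated-tap", 4)
  shares <- source_contributions(scn)
  expect_equal(sum(shares), 1)
  expect_equal(shares[["water"]], 0.247, tolerance = 1e-2)
  scaled <- scn
  scaled$sources <- lapply(scn$sources, function(s) {
    if (s$medium == "water") s$volume_L_day <- s$volume_L_day * 3
    else s$intake_ugkgday <- s$intake_ugkgday * 3
    s
  })
  expect_equal(source_contributions(scaled), shares)

  single <- exposure_scenario("tp-only", 4, 16, list(
    exposure_source("toothpaste", 40),
    exposure_source("water", volume_L_day = 0.442, concentration_mg_L = 0)))
  expect_equal(source_contributions(single)[["toothpaste"]], 1)

  none <- exposure_scenario("empty", 4, 16, list(
    exposure_source("toothpaste", 0),
    exposure_source("water", volume_L_day = 0, concentration_mg_L = 0)))
  expect_error(source_contributions(none), "undefined",
               class = "fluopbpk_domain_error")
})

test_that("kinetic and arithmetic source shares agree for the linear model", {
  scn <- scenario_preset("fluoridated-tap", 4)
  arith <- source_contributions(scn, method = "intake")
  kinetic <- source_contributions(scn, method = "pbpk")
  expect_lt(max(abs(kinetic - arith) / arith), 0.005)
})

test_that("intake-to-absorbed conversion applies the aggregate bioavailability", {
  expect_equal(intake_to_absorbed(0.05, 0.8), 0.04)
  expect_equal(intake_to_absorbed(0.1, 0.8), 0.08)
  expect_equal(intake_to_absorbed(0.123, 1.0), 0.123)
  expect_error(intake_to_absorbed(-0.1), class = "fluopbpk_domain_error")
  expect_error(intake_to_absorbed(0.1, 0), class = "fluopbpk_domain_error")
})

test_that("infusion-rate conversion is exact and invertible", {
  expect_equal(to_infusion_rate(64.9, 16), 7.21e-4, tolerance = 1e-3)
  expect_equal(to_infusion_rate(0, 20), 0)
  r <- to_infusion_rate(37.5, 22)
  expect_equal(r * 1440 * 1000 / 22, 37.5)
})

test_that("scenario presets mirror the study design", {
  s1 <- scenario_preset("ontario-s1", 4)
  expect_equal(s1$water_concentration, 0.505)
  s2 <- scenario_preset("quebec-s2", 8)
  s3 <- scenario_preset("quebec-s3", 8)
  expect_equal(s2$water_concentration, 0.06)
  expect_equal(s3$water_concentration, 0.06)
  # scenario 3 = scenario 2 minus the diet source, all else identical
  expect_setdiff <- setdiff(names(s2$sources), names(s3$sources))
  expect_equal(expect_setdiff, "diet")
  for (m in names(s3$sources)) expect_equal(s3$sources[[m]], s2$sources[[m]])
  expect_error(scenario_preset("nope", 4), "valid presets",
               class = "fluopbpk_config_error")
})

test_that("scenario construction enforces unique media and a single water source", {
  src_w <- exposure_source("water", volume_L_day = 0.4, concentration_mg_L = 0.5)
  expect_error(exposure_scenario("x", 4, 16, list(src_w, src_w)),
               class = "fluopbpk_config_error")
  expect_error(exposure_scenario("x", 4, 16, list(exposure_source("diet", 10))),
               "water", class = "fluopbpk_config_error")
})
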