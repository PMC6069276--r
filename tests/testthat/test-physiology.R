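test_that("reference anthropometry covers the two reference children and rejects others", {
  expect_equal(reference_anthropometry(4), c(body_weight = 16, height = 103))
  expect_equal(reference_anthropometry(8), c(body_weight = 25, height = 127))
  expect_error(reference_anthropometry(6), "no reference anthropometry",
               class = "fluopbpk_config_error")
  expect_equal(
    reference_anthropometry(6, overrides = list(body_weight = 20, height = 115)),
    c(body_weight = 20, height = 115))
})

test_that("anthropometry interpolation is linear and warns outside the validated range", {
  expect_equal(interpolate_anthropometry(5),
               c(body_weight = 16 + 2.25, height = 103 + 6))
  expect_equal(interpolate_anthropometry(7)[["body_weight"]], 16 + 3 * 2.25)
  expect_warning(interpolate_anthropometry(9), "outside the validated range")
  expect_error(interpolate_anthropometry(3), class = "fluopbpk_domain_error")
})

test_that("clearance split matches the two-point lines and their interpolation", {
  expect_equal(clearance_fractions(0),
               c(bone_fraction = 0.90, renal_fraction = 0.10))
  expect_equal(clearance_fractions(18),
               c(bone_fraction = 0.50, renal_fraction = 0.50))
  f4 <- clearance_fractions(4)
  expect_equal(f4[["bone_fraction"]], (90 - (40 / 18) * 4) / 100, tolerance = 1e-12)
  expect_equal(round(unname(f4), 4), c(0.8111, 0.1889))
  expect_equal(clearance_fractions(9),
               c(bone_fraction = 0.70, renal_fraction = 0.30))
  expect_error(clearance_fractions(-1), class = "fluopbpk_domain_error")
  expect_error(clearance_fractions(19), class = "fluopbpk_domain_error")
})

test_that("clearance split is affine, monotone, and sums to one across ages", {
  ages <- seq(0, 18, by = 0.5)
  bone <- vapply(ages, function(a) clearance_fractions(a)[["bone_fraction"]], numeric(1))
  renal <- vapply(ages, function(a) clearance_fractions(a)[["renal_fraction"]], numeric(1))
  expect_true(all(bone + renal == 1))            # exact by construction
  expect_true(all(diff(bone) < 0))
  expect_true(all(diff(renal) > 0))
  expect_equal(max(abs(diff(diff(bone)))), 0, tolerance = 1e-12)  # affine
})

test_that("allometric clearance scaling follows the 0.75 power law", {
  expect_equal(scale_plasma_clearance(70, 0.07, 70), 0.07)
  expect_equal(scale_plasma_clearance(16, 1, 70), (16 / 70)^0.75)
  expect_equal(scale_plasma_clearance(16, 1, 70), 0.3306, tolerance = 1e-3)
  expect_equal(scale_plasma_clearance(25, 1, 70), 0.4620, tolerance = 1e-3)
  # homogeneous in the reference clearance
  expect_equal(scale_plasma_clearance(16, 2 * 0.07, 70),
               2 * scale_plasma_clearance(16, 0.07, 70))
  # invariant under joint scaling of both weights
  expect_equal(scale_plasma_clearance(16, 0.07, 70),
               scale_plasma_clearance(32, 0.07, 140))
  expect_error(scale_plasma_clearance(-1, 0.07, 70), class = "fluopbpk_domain_error")
  expect_error(scale_plasma_clearance(16, 0, 70), class = "fluopbpk_domain_error")
})

test_that("built physiology satisfies its mass and flow invariants", {
  for (age in c(4, 8)) {
    phys <- build_physiology(age)
    expect_true(all(phys$compartments$volume > 0))
    expect_true(all(phys$compartments$blood_flow > 0))
    expect_lt(abs(sum(phys$compartments$blood_flow) - phys$cardiac_output),
              1e-9 * phys$cardiac_output)
    expect_lte(sum(phys$compartments$volume) + phys$blood_volume,
               phys$body_weight)
  }
  # deterministic: repeated construction is bitwise identical
  expect_identical(build_physiology(4), build_physiology(4))
})

test_that("configuration validation rejects incomplete or unbalanced specs", {
  cfg <- default_config()
  broken <- cfg
  broken$compartments <- broken$compartments[-3]   # drop bone
  expect_error(build_physiology(4, config = broken), "bone",
               class = "fluopbpk_config_error")
  unbalanced <- cfg
  unbalanced$compartments[[1]]$flow_fraction_co <-
    unbalanced$compartments[[1]]$flow_fraction_co - 0.1
  expect_error(build_physiology(4, config = unbalanced), "sum to 1",
               class = "fluopbpk_config_error")
  missing_top <- cfg
  missing_top$reference_clearance <- NULL
  expect_error(validate_config(missing_top), "reference_clearance",
               class = "fluopbpk_config_error")
})

test_that("clearance sets partition plasma clearance consistently", {
  for (age in c(4, 8)) {
    cl <- build_clearances(age, reference_anthropometry(age)[["body_weight"]])
    expect_identical(cl$bone_fraction + cl$renal_fraction, 1)
    expect_lt(abs(cl$bone_clearance + cl$renal_clearance - cl$plasma_clearance),
              1e-12 * cl$plasma_clearance)
    expect_gt(cl$plasma_clearance, 0)
  }
})

test_that("daily urine volume interpolates between the configured ages", {
  expect_equal(daily_urine_volume(4), 0.5)
  expect_equal(daily_urine_volume(8), 0.7)
  expect_equal(daily_urine_volume(6), 0.6)
  expect_equal(daily_urine_volume(10), 0.7)  # constant extension
})
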