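bundle4 <- build_model_bundle(4)

test_that("derivatives vanish at the origin and route the infusion into the liver", {
  p0 <- build_ode_params(bundle4, 0)
  zero <- stats::setNames(rep(0, 6), c("blood", "liver", "kidney",
                                       "rest_of_body", "bone", "urine"))
  expect_equal(fluoride_derivatives(0, zero, p0)[[1]], rep(0, 6))

  dose <- 1.44  # mg/day -> 0.001 mg/min
  p1 <- build_ode_params(bundle4, dose)
  d <- fluoride_derivatives(0, zero, p1)[[1]]
  expect_equal(d[2], dose / 1440)
  expect_equal(d[-2], rep(0, 5))
})

test_that("with no dosing, total mass only moves into urine and bone", {
  p0 <- build_ode_params(bundle4, 0)
  state <- c(blood = 0.4, liver = 0.1, kidney = 0.02, rest_of_body = 1.5,
             bone = 0.3, urine = 0.2)
  d <- fluoride_derivatives(0, state, p0)[[1]]
  expect_equal(sum(d), 0, tolerance = 1e-15)                  # closed system
  expect_equal(sum(d[1:4]), -(d[5] + d[6]), tolerance = 1e-12)
})

test_that("derivatives flag non-finite states by component", {
  p0 <- build_ode_params(bundle4, 0)
  bad <- c(blood = NaN, liver = 0, kidney = 0, rest_of_body = 0,
           bone = 0, urine = 0)
  expect_error(fluoride_derivatives(0, bad, p0), "blood",
               class = "fluopbpk_numeric_error")
})

test_that("dose schedule converts daily doses to minute infusion exactly", {
  ds <- dose_schedule(1.0384)
  expect_equal(ds$infusion_rate * 1440, ds$daily_dose_mg, tolerance = 1e-12)
  expect_error(dose_schedule(-1), class = "fluopbpk_domain_error")
})

test_that("zero dose yields identically zero concentrations and excretion", {
  sim <- simulate_fluoride(bundle4, 0, duration_days = 2)
  expect_true(all(sim$arterial == 0))
  expect_true(all(sim$cumulative_urinary == 0))
  expect_equal(unname(sim$per_day_excretion), rep(0, 2))
})

test_that("the dose-response map is linear and mass is conserved", {
  s1 <- simulate_fluoride(bundle4, 0.5, duration_days = 150, out_step_min = 1440)
  s2 <- simulate_fluoride(bundle4, 1.0, duration_days = 150, out_step_min = 1440)
  expect_lt(max(abs(s2$cumulative_urinary[-1] - 2 * s1$cumulative_urinary[-1]) /
                  s2$cumulative_urinary[-1]), 1e-6)
  expect_lt(max(abs(s2$arterial[-1] - 2 * s1$arterial[-1]) / s2$arterial[-1]), 1e-6)

  infused <- s2$dose$daily_dose_mg / 1440 * s2$time_min
  total <- rowSums(s2$amounts) + s2$cumulative_urinary
  expect_lt(max(abs(total - infused)[-1] / infused[-1]), 1e-3)

  expect_true(all(diff(s2$cumulative_urinary) >= 0))
  expect_true(all(diff(s2$cumulative_bone_uptake) >= 0))
})

test_that("numerical solution matches the matrix-exponential solution of the linear system", {
  skip_if_not_installed("Matrix")
  dose <- 1
  p <- build_ode_params(bundle4, dose)
  # d/dt A = M A + b  with states (blood, liver, kidney, rest, bone, urine)
  M <- matrix(0, 6, 6)
  Qli <- p$Q[["liver"]]; Qk <- p$Q[["kidney"]]; Qrb <- p$Q[["rest_of_body"]]
  M[1, 1] <- -(Qli + Qk + Qrb + p$CL_renal + p$CL_bone) / p$V_blood
  M[1, 2] <- Qli / p$VP[["liver"]]
  M[1, 3] <- Qk / p$VP[["kidney"]]
  M[1, 4] <- Qrb / p$VP[["rest_of_body"]]
  M[1, 5] <- p$CL_bone / p$VP[["bone"]]
  M[2, 1] <- Qli / p$V_blood;  M[2, 2] <- -Qli / p$VP[["liver"]]
  M[3, 1] <- Qk / p$V_blood;   M[3, 3] <- -Qk / p$VP[["kidney"]]
  M[4, 1] <- Qrb / p$V_blood;  M[4, 4] <- -Qrb / p$VP[["rest_of_body"]]
  M[5, 1] <- p$CL_bone / p$V_blood; M[5, 5] <- -p$CL_bone / p$VP[["bone"]]
  M[6, 1] <- p$CL_renal / p$V_blood
  b <- c(0, p$infusion_rate, 0, 0, 0, 0)
  aug <- rbind(cbind(M, b), 0)   # constant forcing via augmented system

  sim <- simulate_fluoride(bundle4, dose, duration_days = 100,
                           out_step_min = 1440)
  for (day in c(1, 10, 100)) {
    t_min <- day * 1440
    exact <- as.numeric(Matrix::expm(aug * t_min) %*% c(rep(0, 6), 1))[1:6]
    got <- c(sim$amounts[sim$time_min == t_min, ],
             sim$cumulative_urinary[sim$time_min == t_min])
    expect_equal(unname(got), exact[c(1:5, 6)], tolerance = 1e-6)
  }
})

test_that("steady-state daily excretion is the day-150 minus day-149 amount", {
  sim <- simulate_fluoride(bundle4, 1, duration_days = 150, out_step_min = 1440)
  d150 <- sim$cumulative_urinary[sim$time_min == 150 * 1440] -
    sim$cumulative_urinary[sim$time_min == 149 * 1440]
  expect_equal(steady_state_daily_excretion(sim), unname(d150))
  expect_error(steady_state_daily_excretion(
    simulate_fluoride(bundle4, 1, duration_days = 10, out_step_min = 1440)),
    "insufficient duration", class = "fluopbpk_domain_error")
  # definitional check on a constant-excretion synthetic series
  expect_equal(steady_state_daily_excretion(fake_sim(rep(0.37, 200))), 0.37)
  expect_equal(steady_state_daily_excretion(
    simulate_fluoride(bundle4, 0, duration_days = 150, out_step_min = 1440)), 0)
})

test_that("time to steady state matches the closed form on a geometric approach", {
  d <- 1:300
  series <- 1 - exp(-d / 30)
  expect_equal(time_to_steady_state(series, rel_tol = 0.01), 139L)  # ceil(-30 log 0.01)
  expect_equal(time_to_steady_state(rep(2.5, 10)), 1L)
  expect_error(time_to_steady_state(series, rel_tol = 0), class = "fluopbpk_domain_error")
  expect_error(time_to_steady_state(series, rel_tol = 0.5), class = "fluopbpk_domain_error")
  still_rising <- cumsum(rep(1, 20))
  expect_warning(res <- time_to_steady_state(still_rising, rel_tol = 0.01),
                 "not converged")
  expect_true(is.na(res))
})

test_that("daily excretion converges monotonically after the initial transient", {
  sim <- simulate_fluoride(bundle4, 1, duration_days = 200, out_step_min = 1440)
  final <- sim$per_day_excretion[[200]]
  gap <- abs(sim$per_day_excretion - final) / final
  expect_true(all(diff(gap[5:199]) < 0))
  expect_lte(time_to_steady_state(sim, rel_tol = 0.01), 150)
})

test_that("24-h venous AUC integrates correctly and is grid-robust", {
  # rectangle oracle on a constant synthetic series
  tgrid <- seq(0, 2 * 1440, by = 60)
  flat <- fake_sim(per_day = c(1, 1), time_min = tgrid,
                   venous = rep(0.25, length(tgrid)), duration_days = 2)
  expect_equal(auc_24h(flat, 2), 1440 * 0.25)

  zero <- simulate_fluoride(bundle4, 0, duration_days = 2)
  expect_equal(auc_24h(zero, 1), 0)

  fine <- simulate_fluoride(bundle4, 1, duration_days = 5, out_step_min = 15)
  coarse <- simulate_fluoride(bundle4, 1, duration_days = 5, out_step_min = 60)
  expect_lt(rel_err(auc_24h(coarse, 5), auc_24h(fine, 5)), 1e-3)
  expect_error(auc_24h(fine, 6), class = "fluopbpk_domain_error")
})

test_that("urinary concentration is the excretion to urine-volume ratio", {
  expect_equal(urinary_concentration(0.5, 0.5), 1.0)
  expect_equal(urinary_concentration(0.423, 0.5), 0.846)
  expect_equal(urinary_concentration(0, 0.5), 0)
  expect_error(urinary_concentration(0.5, 0), class = "fluopbpk_domain_error")
})

test_that("with an irreversible bone sink the urinary fraction is CL_r/(CL_r+CL_b)", {
  sink_bundle <- build_model_bundle(4, config = sink_config())
  frac <- unit_steady_state_excretion(sink_bundle, use_cache = FALSE)
  cl <- sink_bundle$clearances
  expect_equal(frac, cl$renal_clearance / (cl$renal_clearance + cl$bone_clearance),
               tolerance = 0.01)
})

test_that("steady-state excretion is robust to solver step refinement", {
  a <- simulate_fluoride(bundle4, 1, duration_days = 150, out_step_min = 1440,
                         max_step = 60)
  b <- simulate_fluoride(bundle4, 1, duration_days = 150, out_step_min = 1440,
                         max_step = 30)
  expect_lt(rel_err(steady_state_daily_excretion(a),
                    steady_state_daily_excretion(b)), 1e-3)
})

test_that("simulation summaries and exports expose the tidy series", {
  sim <- simulate_fluoride(bundle4, 1, duration_days = 150, out_step_min = 1440)
  df <- as.data.frame(sim)
  expect_equal(nrow(df), 151)
  expect_true(all(c("time_min", "arterial_mg_L", "venous_mg_L",
                    "cumulative_urinary_mg") %in% names(df)))
  s <- sim_summary(sim)
  expect_equal(s$steady_state_daily_excretion_mg,
               unname(steady_state_daily_excretion(sim)))
  expect_true(s$time_to_steady_state_days <= 150)
})
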