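# Flow-limited compartmental model of fluoride disposition.
#
# Structure: a well-mixed blood compartment feeding liver, kidney and
# rest-of-body by perfusion (flow-limited, tissue:plasma partition
# coefficients), a continuous zero-order infusion of the absorbed daily dose
# into the liver, renal elimination to urine (CL_renal acting on the
# configured driving concentration), and bone exchange rate-limited by bone
# clearance. In the default "equilibrating" bone mode the bone pool has a
# finite capacity set by its partition coefficient, so net skeletal uptake
# decays as bone fills and daily urinary excretion approaches the absorbed
# dose; in "sink" mode bone uptake is irreversible and never saturates.

#' Constant-infusion dose schedule
#'
#' Converts an absorbed daily dose into the minute-based hepatic infusion
#' rate used by the engine: `infusion_rate = daily_dose / 1440`.
#'
#' @param daily_dose_mg Absorbed daily dose in mg/day (non-negative).
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(daily_dose_mg) {
  if (!is_scalar_number(daily_dose_mg) || daily_dose_mg < 0) {
    abort_domain("daily_dose_mg must be a single non-negative number")
  }
  structure(
    list(infusion_rate = daily_dose_mg / 1440,
         daily_dose_mg = daily_dose_mg,
         route = "constant"),
    class = "dose_schedule"
  )
}

.state_names <- c("blood", "liver", "kidney", "rest_of_body", "bone", "urine")

#' Assemble the numeric parameter set for the ODE right-hand side
#'
#' @param bundle A [build_model_bundle()] object.
#' @param dose_mg_day Absorbed daily dose in mg/day.
#' @return A named list consumed by [fluoride_derivatives()].
#' @export
build_ode_params <- function(bundle, dose_mg_day) {
  phys <- bundle$physiology
  comp <- phys$compartments
  idx <- match(c("liver", "kidney", "bone", "rest_of_body"), comp$name)
  list(
    V_blood = phys$blood_volume,
    Q = stats::setNames(comp$blood_flow[idx], comp$name[idx]),
    VP = stats::setNames(comp$volume[idx] * comp$partition_coefficient[idx],
                         comp$name[idx]),
    CL_renal = bundle$clearances$renal_clearance,
    CL_bone = bundle$clearances$bone_clearance,
    infusion_rate = dose_schedule(dose_mg_day)$infusion_rate,
    bone_mode = bundle$config$bone_mode,
    renal_driver = bundle$config$renal_driver
  )
}

#' Mass-balance derivatives of the fluoride model
#'
#' State vector (amounts in mg): blood, liver, kidney, rest_of_body, bone,
#' urine. For each perfused tissue `t`,
#' `dA_t/dt = Q_t * (C_art - A_t / (V_t * P_t))` with the infusion added to
#' the liver; renal elimination `CL_renal * C_driving` feeds the cumulative
#' urine state; bone exchange is `CL_bone * (C_art - C_bone / P_bone)`
#' (equilibrating) or `CL_bone * C_art` (sink).
#'
#' @param t Time (min); unused (autonomous system) but part of the solver
#'   interface.
#' @param state Named state vector of amounts (mg).
#' @param params Parameter list from [build_ode_params()].
#' @return A list whose first element is the vector of time derivatives.
#' @export
fluoride_derivatives <- function(t, state, params) {
  bad <- !is.finite(state) | state < -1e-9
  if (any(bad)) {
    abort_numeric(sprintf(
      "integration failure: non-finite or negative state in component(s) %s at t = %g min",
      paste(.state_names[bad], collapse = ", "), t))
  }
  C_art <- state[[1]] / params$V_blood
  Cv_li <- state[[2]] / params$VP[["liver"]]
  Cv_k  <- state[[3]] / params$VP[["kidney"]]
  Cv_rb <- state[[4]] / params$VP[["rest_of_body"]]
  C_bone_eq <- state[[5]] / params$VP[["bone"]]

  renal_conc <- if (params$renal_driver == "arterial") C_art else Cv_k
  E_renal <- params$CL_renal * renal_conc
  F_bone <- if (params$bone_mode == "equilibrating") {
    params$CL_bone * (C_art - C_bone_eq)
  } else {
    params$CL_bone * C_art
  }

  d_liver <- params$Q[["liver"]] * (C_art - Cv_li) + params$infusion_rate
  d_kidney <- params$Q[["kidney"]] * (C_art - Cv_k)
  d_rest <- params$Q[["rest_of_body"]] * (C_art - Cv_rb)
  d_blood <- params$Q[["liver"]] * (Cv_li - C_art) +
    params$Q[["kidney"]] * (Cv_k - C_art) +
    params$Q[["rest_of_body"]] * (Cv_rb - C_art) -
    E_renal - F_bone
  list(c(d_blood, d_liver, d_kidney, d_rest, F_bone, E_renal))
}

# mixed venous concentration series, computed from the state matrix
.venous_series <- function(states, params) {
  C_art <- states[, "blood"] / params$V_blood
  Cv_li <- states[, "liver"] / params$VP[["liver"]]
  Cv_k <- states[, "kidney"] / params$VP[["kidney"]]
  Cv_rb <- states[, "rest_of_body"] / params$VP[["rest_of_body"]]
  C_bone_eq <- states[, "bone"] / params$VP[["bone"]]
  F_bone <- if (params$bone_mode == "equilibrating") {
    params$CL_bone * (C_art - C_bone_eq)
  } else {
    params$CL_bone * C_art
  }
  E_k <- if (params$renal_driver == "kidney_exit") params$CL_renal * Cv_k else 0
  Q <- params$Q
  (Q[["liver"]] * Cv_li + Q[["kidney"]] * Cv_k - E_k +
      Q[["rest_of_body"]] * Cv_rb + Q[["bone"]] * C_art - F_bone) / sum(Q)
}

#' Simulate continuous fluoride exposure
#'
#' Integrates the model under a constant hepatic infusion, with daily (or
#' finer) checkpoints, and returns concentration/amount series plus per-day
#' urinary excretion. A stiff-capable solver is used; the integration is
#' checked for mass conservation (total infused vs. total accounted) to
#' 0.1%.
#'
#' @param bundle A [build_model_bundle()] object.
#' @param dose_mg_day Absorbed daily dose (mg/day) infused into the liver.
#' @param duration_days Simulated span in days (>= 1).
#' @param out_step_min Output grid spacing in minutes; must divide 1440.
#' @param rtol,atol Solver tolerances (relative; absolute in mg).
#' @param max_step Maximum internal solver step (min), default unrestricted.
#' @return An object of class `fluoride_sim` with elements `time_min`,
#'   `arterial`, `venous` (mg/L), `amounts` (mg, one column per state),
#'   `cumulative_urinary`, `cumulative_bone_uptake` (mg),
#'   `per_day_excretion` (mg/day, indexed by day) and dosing metadata.
#' @export
simulate_fluoride <- function(bundle, dose_mg_day, duration_days = 150,
                              out_step_min = 60, rtol = 1e-8, atol = 1e-12,
                              max_step = NULL) {
  if (!is_scalar_number(duration_days) || duration_days < 1) {
    abort_domain("duration_days must be >= 1 day")
  }
  if (!is_scalar_number(out_step_min) || out_step_min <= 0 ||
      1440 %% out_step_min != 0) {
    abort_domain("out_step_min must be a positive divisor of 1440 minutes")
  }
  params <- build_ode_params(bundle, dose_mg_day)
  times <- seq(0, duration_days * 1440, by = out_step_min)
  y0 <- stats::setNames(rep(0, 6), .state_names)
  out <- deSolve::lsoda(
    y = y0, times = times, func = fluoride_derivatives, parms = params,
    rtol = rtol, atol = atol,
    hmax = if (is.null(max_step)) Inf else max_step
  )
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    abort_numeric(sprintf(
      "solver failed to converge; last valid time %g min",
      out[nrow(out), 1]))
  }
  states <- out[, .state_names, drop = FALSE]

  infused <- params$infusion_rate * times
  total <- rowSums(states)
  if (dose_mg_day > 0) {
    rel_err <- max(abs(total - infused)[-1] / infused[-1])
    if (rel_err > 1e-3) {
      abort_numeric(sprintf("mass-balance violation: %.3g relative error", rel_err))
    }
  }

  day_rows <- which(times %% 1440 == 0)
  cum_ur <- states[, "urine"]
  per_day <- diff(cum_ur[day_rows])
  names(per_day) <- seq_along(per_day)

  structure(
    list(
      time_min = times,
      arterial = states[, "blood"] / params$V_blood,
      venous = .venous_series(states, params),
      amounts = states[, c("blood", "liver", "kidney", "rest_of_body", "bone")],
      cumulative_urinary = cum_ur,
      cumulative_bone_uptake = states[, "bone"],
      per_day_excretion = per_day,
      dose = dose_schedule(dose_mg_day),
      duration_days = duration_days,
      out_step_min = out_step_min,
      age_years = bundle$age_years,
      body_weight = bundle$physiology$body_weight,
      daily_urine_volume = bundle$physiology$daily_urine_volume,
      bone_mode = params$bone_mode
    ),
    class = "fluoride_sim"
  )
}

#' @export
print.fluoride_sim <- function(x, ...) {
  cat(sprintf(
    "<fluoride_sim> %g days, dose %.4g mg/day, age %g y; day-%d excretion %.4g mg/day\n",
    x$duration_days, x$dose$daily_dose_mg, x$age_years,
    length(x$per_day_excretion),
    x$per_day_excretion[[length(x$per_day_excretion)]]))
  invisible(x)
}

#' @export
as.data.frame.fluoride_sim <- function(x, ...) {
  data.frame(
    time_min = x$time_min,
    arterial_mg_L = x$arterial,
    venous_mg_L = x$venous,
    x$amounts,
    cumulative_urinary_mg = x$cumulative_urinary,
    check.names = FALSE
  )
}

#' Compact JSON-ready summary of a simulation
#'
#' @param result A `fluoride_sim` object covering at least 150 days.
#' @param rel_tol Convergence tolerance passed to [time_to_steady_state()].
#' @return A list with steady-state excretion, time to steady state, and the
#'   final-day venous AUC.
#' @export
sim_summary <- function(result, rel_tol = 0.01) {
  list(
    dose_mg_day = result$dose$daily_dose_mg,
    steady_state_daily_excretion_mg = steady_state_daily_excretion(result),
    time_to_steady_state_days = time_to_steady_state(result, rel_tol),
    auc_24h_final_day = auc_24h(result, result$duration_days)
  )
}

#' Steady-state 24-h urinary excretion
#'
#' The day-150 daily excreted amount, computed as the cumulative urinary
#' fluoride at day 150 minus that at day 149.
#'
#' @param result A `fluoride_sim` (or any list carrying `per_day_excretion`).
#' @param day Day index defining "steady state"; default 150.
#' @return Excreted amount in mg/day.
#' @export
steady_state_daily_excretion <- function(result, day = 150L) {
  per_day <- result$per_day_excretion
  if (length(per_day) < day) {
    abort_domain(sprintf(
      "insufficient duration: result covers %d days but steady state is defined at day %d",
      length(per_day), day))
  }
  per_day[[day]]
}

#' First day within tolerance of the asymptotic daily excretion
#'
#' Scans the per-day excretion series for the first day whose value is
#' within `rel_tol` (relative) of the final simulated day's value. Returns
#' `NA` with a warning if only the final day itself qualifies while the
#' series is still moving ("not converged").
#'
#' @param result A `fluoride_sim` object, or a bare numeric per-day series.
#' @param rel_tol Relative tolerance, in (0, 0.1].
#' @return Integer day index, or `NA_integer_` if not converged.
#' @export
time_to_steady_state <- function(result, rel_tol = 0.01) {
  if (!is_scalar_number(rel_tol) || rel_tol <= 0 || rel_tol > 0.1) {
    abort_domain("rel_tol must lie in (0, 0.1]")
  }
  per_day <- if (is.numeric(result)) result else result$per_day_excretion
  n <- length(per_day)
  if (n < 1) abort_domain("empty excretion series")
  final <- per_day[[n]]
  if (final <= 0) abort_domain("final daily excretion is not positive")
  ok <- abs(per_day - final) / final <= rel_tol
  d <- which(ok)[1]
  if (d == n && n > 1 && abs(per_day[[n - 1]] - final) / final > rel_tol) {
    warning("excretion series has not converged within the simulated span",
            call. = FALSE)
    return(NA_integer_)
  }
  as.integer(d)
}

#' 24-h area under the venous concentration curve
#'
#' Trapezoidal integral of the venous fluoride concentration over one
#' simulated day.
#'
#' @param result A `fluoride_sim` object.
#' @param day_index Day to integrate over (1-based).
#' @return AUC in mg.min/L (non-negative).
#' @export
auc_24h <- function(result, day_index) {
  if (!is_scalar_number(day_index) || day_index < 1 ||
      day_index > result$duration_days) {
    abort_domain(sprintf("day_index must lie within the simulated span (1..%d)",
                         result$duration_days))
  }
  lo <- (day_index - 1) * 1440
  hi <- day_index * 1440
  sel <- result$time_min >= lo & result$time_min <= hi
  t <- result$time_min[sel]
  y <- result$venous[sel]
  if (length(t) < 2) {
    abort_domain("output grid too coarse to integrate over one day")
  }
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Convert a daily excreted amount to a urinary concentration
#'
#' @param daily_excretion Excreted amount in mg/day (non-negative).
#' @param daily_urine_volume Daily urine volume in L/day (positive).
#' @return Concentration in mg/L; a `calibrated` attribute on the input is
#'   preserved.
#' @export
urinary_concentration <- function(daily_excretion, daily_urine_volume) {
  if (!is_scalar_number(daily_excretion) || daily_excretion < 0) {
    abort_domain("daily_excretion must be a single non-negative number")
  }
  stopifnot_scalar_positive(daily_urine_volume, "daily_urine_volume")
  out <- as.numeric(daily_excretion) / daily_urine_volume
  if (isTRUE(attr(daily_excretion, "calibrated"))) attr(out, "calibrated") <- TRUE
  out
}

# memoisation key for a bundle's unit steady-state response
.bundle_key <- function(bundle) {
  comp <- bundle$physiology$compartments
  paste(
    format(c(bundle$age_years, bundle$physiology$body_weight,
             bundle$physiology$blood_volume, comp$volume, comp$blood_flow,
             comp$partition_coefficient, bundle$clearances$renal_clearance,
             bundle$clearances$bone_clearance), digits = 17),
    bundle$config$bone_mode, bundle$config$renal_driver,
    collapse = "|"
  )
}

#' Steady-state daily excretion per unit dose
#'
#' The model is linear in dose, so the day-150 daily urinary excretion for a
#' 1 mg/day absorbed dose fully characterizes the forward map at steady
#' state. The result is memoised per model parameterization.
#'
#' @param bundle A [build_model_bundle()] object.
#' @param use_cache Reuse a previously computed response for an identical
#'   parameterization.
#' @return Dimensionless fraction: mg/day excreted per mg/day absorbed.
#' @export
unit_steady_state_excretion <- function(bundle, use_cache = TRUE) {
  key <- .bundle_key(bundle)
  if (use_cache && !is.null(.fluo_cache[[key]])) return(.fluo_cache[[key]])
  sim <- simulate_fluoride(bundle, 1, duration_days = 150, out_step_min = 1440)
  val <- steady_state_daily_excretion(sim)
  .fluo_cache[[key]] <- val
  val
}

#' Predicted steady-state 24-h urinary excretion for a dose
#'
#' Forward prediction of the daily excreted urinary fluoride at steady state
#' for an absorbed daily dose, optionally applying the bundle's empirical
#' calibration factor (see [apply_adjustment()]).
#'
#' @inheritParams unit_steady_state_excretion
#' @param dose_mg_day Absorbed daily dose in mg/day.
#' @param calibrated Apply the bundle's adjustment factor; defaults to doing
#'   so whenever the bundle carries one.
#' @return Excreted amount in mg/day; carries `calibrated = TRUE` when the
#'   factor has been applied.
#' @export
predict_urinary_excretion <- function(bundle, dose_mg_day,
                                      calibrated = !is.null(bundle$adjustment_factor),
                                      use_cache = TRUE) {
  if (!is_scalar_number(dose_mg_day) || dose_mg_day < 0) {
    abort_domain("dose_mg_day must be a single non-negative number")
  }
  val <- if (use_cache) {
    unit_steady_state_excretion(bundle) * dose_mg_day
  } else {
    sim <- simulate_fluoride(bundle, dose_mg_day, duration_days = 150,
                             out_step_min = 1440)
    steady_state_daily_excretion(sim)
  }
  if (calibrated) {
    if (is.null(bundle$adjustment_factor)) {
      abort_config("bundle carries no adjustment factor; build it with one or set calibrated = FALSE")
    }
    val <- apply_adjustment(val, bundle$adjustment_factor)
  }
  val
}
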