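# Local sensitivity analysis: normalized one-sided finite-difference
# sensitivity indices for every model parameter, computed for the 24-h
# steady-state urinary excretion (Aexc) and the 24-h venous-concentration
# AUC (AUC_vc) metrics.

#' Parameters covered by the sensitivity screen
#'
#' @return Character vector of perturbable parameter names.
#' @export
sensitivity_parameters <- function() {
  c("body_weight", "oral_absorption_fraction", "renal_clearance",
    "bone_clearance", "bone_volume", "bone_partition_coefficient",
    "blood_volume", "cardiac_output", "liver_volume", "kidney_volume",
    "rest_of_body_volume", "water_intake", "diet_intake",
    "toothpaste_intake", "soil_intake", "air_intake")
}

#' Normalized finite-difference sensitivity index
#'
#' `SI = ((O_2 - O_i) / (P_2 - P_i)) * (P_i / O_i)`, the normalized
#' (unit-free) elasticity estimated from a single perturbed run. With the
#' standard 2% reduction, `P_2/P_i = 0.98` and the index reduces to
#' `((O_2/O_i) - 1) / -0.02`. A negative index means the output rises when
#' the parameter falls.
#'
#' @param baseline_output,perturbed_output Output at the initial and
#'   perturbed parameter value.
#' @param relative_change `(P_2 - P_i)/P_i`; the conventional 2% reduction
#'   is `-0.02`.
#' @return Dimensionless sensitivity index.
#' @export
normalized_sensitivity <- function(baseline_output, perturbed_output,
                                   relative_change = -0.02) {
  if (!is_scalar_number(baseline_output) || baseline_output == 0) {
    abort_domain("sensitivity index undefined: baseline output is zero or non-finite")
  }
  if (!is_scalar_number(relative_change) || relative_change == 0) {
    abort_domain("relative_change must be a non-zero number")
  }
  ((perturbed_output - baseline_output) / baseline_output) / relative_change
}

# Build the (bundle, dose) pair for a scenario with one parameter scaled by
# `factor`. Perturbations deliberately bypass the construction-time
# invariants (a perturbed physiology is a probe, not a reference child).
.perturbed_system <- function(scenario, config, parameter = NULL, factor = 1) {
  oaf <- 1
  if (!is.null(parameter)) {
    if (!parameter %in% sensitivity_parameters()) {
      abort_config(sprintf("unknown sensitivity parameter '%s'", parameter))
    }
    intake_map <- c(water_intake = "water", diet_intake = "diet",
                    toothpaste_intake = "toothpaste", soil_intake = "soil",
                    air_intake = "air")
    if (parameter == "body_weight") {
      scenario$body_weight <- scenario$body_weight * factor
    } else if (parameter == "oral_absorption_fraction") {
      oaf <- factor
    } else if (parameter %in% names(intake_map)) {
      medium <- intake_map[[parameter]]
      src <- scenario$sources[[medium]]
      if (is.null(src)) {
        abort_config(sprintf("scenario '%s' has no '%s' source to perturb",
                             scenario$label, medium))
      }
      if (medium == "water") {
        src$volume_L_day <- src$volume_L_day * factor
      } else {
        src$intake_ugkgday <- src$intake_ugkgday * factor
      }
      scenario$sources[[medium]] <- src
    }
  }
  bundle <- build_model_bundle(scenario$age_years, config,
                               body_weight = scenario$body_weight)
  if (!is.null(parameter)) {
    phys <- bundle$physiology
    cl <- bundle$clearances
    comp_scale <- function(name, col) {
      i <- match(name, phys$compartments$name)
      phys$compartments[[col]][i] <<- phys$compartments[[col]][i] * factor
    }
    switch(parameter,
      renal_clearance = {
        cl$renal_clearance <- cl$renal_clearance * factor
      },
      bone_clearance = {
        cl$bone_clearance <- cl$bone_clearance * factor
      },
      cardiac_output = {
        phys$cardiac_output <- phys$cardiac_output * factor
        phys$compartments$blood_flow <- phys$compartments$blood_flow * factor
      },
      blood_volume = phys$blood_volume <- phys$blood_volume * factor,
      bone_volume = comp_scale("bone", "volume"),
      liver_volume = comp_scale("liver", "volume"),
      kidney_volume = comp_scale("kidney", "volume"),
      rest_of_body_volume = comp_scale("rest_of_body", "volume"),
      bone_partition_coefficient = comp_scale("bone", "partition_coefficient"),
      NULL
    )
    cl$plasma_clearance <- cl$renal_clearance + cl$bone_clearance
    cl$renal_fraction <- cl$renal_clearance / cl$plasma_clearance
    cl$bone_fraction <- 1 - cl$renal_fraction
    bundle$physiology <- phys
    bundle$clearances <- cl
  }
  list(bundle = bundle, dose_mg_day = scenario_daily_dose(scenario) * oaf)
}

# Aexc (mg/day) and AUC_vc (mg.min/L) at day 150 for one system
.sensitivity_outputs <- function(system) {
  sim <- simulate_fluoride(system$bundle, system$dose_mg_day,
                           duration_days = 150, out_step_min = 60)
  c(Aexc = steady_state_daily_excretion(sim), AUC_vc = auc_24h(sim, 150))
}

#' Sensitivity index of one parameter
#'
#' Perturbs the parameter by a one-sided 2% reduction, re-simulates to
#' steady state (day 150), and returns the normalized index for the chosen
#' output metric.
#'
#' @param parameter A name from [sensitivity_parameters()].
#' @param metric `"Aexc"` (24-h urinary excretion) or `"AUC_vc"` (24-h
#'   venous AUC).
#' @param age_years Reference child age (4 or 8).
#' @param scenario Exposure scenario; defaults to the `fluoridated-tap`
#'   preset for `age_years`.
#' @param config Model configuration.
#' @param delta Fractional reduction of the parameter (default 0.02).
#' @param baseline Optional precomputed baseline output pair (named vector
#'   with `Aexc` and `AUC_vc`), reused across parameters by the screen.
#' @return One-row data frame: parameter, age, metric, sensitivity index,
#'   baseline and perturbed outputs.
#' @export
sensitivity_index <- function(parameter, metric = c("Aexc", "AUC_vc"),
                              age_years = 4, scenario = NULL,
                              config = default_config(), delta = 0.02,
                              baseline = NULL) {
  metric <- match.arg(metric)
  if (!is_scalar_number(delta) || delta <= 0 || delta >= 1) {
    abort_domain("delta must lie in (0, 1)")
  }
  scenario <- scenario %||% scenario_preset("fluoridated-tap", age_years)
  if (is.null(baseline)) {
    baseline <- .sensitivity_outputs(.perturbed_system(scenario, config))
  }
  perturbed <- .sensitivity_outputs(
    .perturbed_system(scenario, config, parameter, factor = 1 - delta))
  si <- normalized_sensitivity(baseline[[metric]], perturbed[[metric]],
                               relative_change = -delta)
  data.frame(parameter = parameter, age_years = scenario$age_years,
             metric = metric, si = si,
             baseline_output = baseline[[metric]],
             perturbed_output = perturbed[[metric]],
             stringsAsFactors = FALSE)
}

#' Screen all parameters for influential sensitivity indices
#'
#' Computes the normalized sensitivity index of every parameter for both
#' output metrics and both reference ages, and reports the parameters whose
#' largest absolute index reaches the threshold, ranked by that maximum.
#'
#' @param threshold Minimum absolute index for inclusion (default 0.05).
#' @param ages Ages to screen.
#' @param metrics Output metrics to screen.
#' @param preset Scenario preset supplying the exposure baseline.
#' @param parameters Parameters to screen.
#' @param config Model configuration.
#' @param delta Fractional parameter reduction.
#' @return Long data frame (parameter, age_years, metric, si, ...) limited
#'   to parameters passing the screen and ordered by decreasing maximum
#'   absolute index; the complete unfiltered table is in `attr(, "full")`.
#' @export
screen_parameters <- function(threshold = 0.05, ages = c(4, 8),
                              metrics = c("Aexc", "AUC_vc"),
                              preset = "fluoridated-tap",
                              parameters = sensitivity_parameters(),
                              config = default_config(), delta = 0.02) {
  if (!is_scalar_number(threshold) || threshold < 0) {
    abort_domain("threshold must be a non-negative number")
  }
  rows <- list()
  for (age in ages) {
    scenario <- scenario_preset(preset, age)
    baseline <- .sensitivity_outputs(.perturbed_system(scenario, config))
    for (p in parameters) {
      perturbed <- .sensitivity_outputs(
        .perturbed_system(scenario, config, p, factor = 1 - delta))
      for (m in metrics) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, age_years = age, metric = m,
          si = normalized_sensitivity(baseline[[m]], perturbed[[m]], -delta),
          baseline_output = baseline[[m]], perturbed_output = perturbed[[m]],
          stringsAsFactors = FALSE)
      }
    }
  }
  full <- do.call(rbind, rows)
  max_abs <- tapply(abs(full$si), full$parameter, max)
  keep <- names(max_abs)[max_abs >= threshold]
  out <- full[full$parameter %in% keep, , drop = FALSE]
  out <- out[order(-max_abs[out$parameter], out$parameter, out$age_years,
                   out$metric), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full
  attr(out, "threshold") <- threshold
  out
}
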