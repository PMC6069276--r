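# Age-specific physiology: anthropometry, compartment volumes and flows,
# cardiac output and the age-dependent split of plasma clearance into bone
# and renal clearance.

.reference_children <- data.frame(
  age_years = c(4, 8),
  body_weight = c(16, 25),  # kg, growth-chart 50th percentile
  height = c(103, 127)      # cm
)

#' Reference anthropometry for the built-in children
#'
#' Body weight and height of the 4- and 8-year-old reference children
#' (growth-chart 50th-percentile values). Other ages require explicit
#' overrides; see [interpolate_anthropometry()] for the interpolation used
#' when matching validation cohorts of intermediate ages.
#'
#' @param age_years Age in years; 4 or 8 for built-in values.
#' @param overrides Optional list with `body_weight` (kg) and `height` (cm)
#'   for ages without built-in values.
#' @return Named numeric vector `c(body_weight =, height =)`.
#' @examples
#' reference_anthropometry(4)
#' @export
reference_anthropometry <- function(age_years, overrides = NULL) {
  stopifnot_scalar_positive(age_years, "age_years")
  if (!is.null(overrides)) {
    if (!is_scalar_number(overrides$body_weight) || overrides$body_weight <= 0 ||
        !is_scalar_number(overrides$height) || overrides$height <= 0) {
      abort_config("overrides must supply positive body_weight and height")
    }
    return(c(body_weight = overrides$body_weight, height = overrides$height))
  }
  i <- match(age_years, .reference_children$age_years)
  if (is.na(i)) {
    abort_config(sprintf(
      "no reference anthropometry for age %s years; supply overrides", age_years))
  }
  c(body_weight = .reference_children$body_weight[i],
    height = .reference_children$height[i])
}

#' Interpolated anthropometry between the reference children
#'
#' Linear interpolation of body weight and height between the 4- and
#' 8-year-old reference children, used when building models for validation
#' cohorts of intermediate ages. Ages above 8 are linearly extrapolated with
#' an out-of-validated-range warning.
#'
#' @inheritParams reference_anthropometry
#' @return Named numeric vector `c(body_weight =, height =)`.
#' @export
interpolate_anthropometry <- function(age_years) {
  stopifnot_scalar_positive(age_years, "age_years")
  if (age_years < 4) {
    abort_domain("anthropometry interpolation is defined for ages >= 4 years")
  }
  if (age_years > 8) {
    warning("age > 8 years is outside the validated range; extrapolating anthropometry",
            call. = FALSE)
  }
  ref <- .reference_children
  slope_bw <- diff(ref$body_weight) / diff(ref$age_years)
  slope_h <- diff(ref$height) / diff(ref$age_years)
  c(body_weight = ref$body_weight[1] + (age_years - 4) * slope_bw,
    height = ref$height[1] + (age_years - 4) * slope_h)
}

#' Age-dependent split of plasma clearance into bone and renal clearance
#'
#' Bone and renal clearance account for 90% and 10% of plasma clearance at
#' birth and 50% each at maturity (18 years); the split is assumed linear in
#' age between those two anchor points, following longitudinal dog data.
#'
#' @param age_years Age in years, within \[0, 18\].
#' @return Named numeric vector `c(bone_fraction =, renal_fraction =)`;
#'   the two fractions sum to 1 exactly.
#' @examples
#' clearance_fractions(4)
#' @export
clearance_fractions <- function(age_years) {
  if (!is_scalar_number(age_years) || age_years < 0 || age_years > 18) {
    abort_domain("age_years must be within [0, 18]; the clearance split lines are defined only on this span")
  }
  bone <- (90 - (40 / 18) * age_years) / 100
  c(bone_fraction = bone, renal_fraction = 1 - bone)
}

#' Allometric scaling of plasma clearance
#'
#' Scales a reference plasma clearance to another body weight using the
#' standard three-quarter power law:
#' `reference_clearance * (body_weight / reference_bw)^0.75`.
#'
#' @param body_weight Target body weight (kg).
#' @param reference_clearance Reference plasma clearance (L/min).
#' @param reference_bw Reference body weight (kg).
#' @return Plasma clearance in L/min at `body_weight`.
#' @export
scale_plasma_clearance <- function(body_weight, reference_clearance, reference_bw) {
  stopifnot_scalar_positive(body_weight, "body_weight")
  stopifnot_scalar_positive(reference_clearance, "reference_clearance")
  stopifnot_scalar_positive(reference_bw, "reference_bw")
  reference_clearance * (body_weight / reference_bw)^0.75
}

#' Build an age-specific physiological parameter set
#'
#' Assembles compartment volumes (fractions of body weight, 1 kg/L density),
#' blood flows (fractions of cardiac output), blood volume, cardiac output
#' and daily urine volume for one reference child. The construction enforces
#' the type invariants: all volumes and flows positive, compartment flows
#' summing to cardiac output, and total volume (compartments plus blood) not
#' exceeding body weight.
#'
#' @param age_years Age in years.
#' @param body_weight,height Optional overrides (kg, cm); defaults come from
#'   [reference_anthropometry()] and therefore require `age_years` in
#'   \{4, 8\} unless both are supplied.
#' @param config Model configuration, see [default_config()].
#' @return An object of class `child_physiology`.
#' @export
build_physiology <- function(age_years, body_weight = NULL, height = NULL,
                             config = default_config()) {
  validate_config(config)
  if (is.null(body_weight) || is.null(height)) {
    anth <- if (age_years %in% .reference_children$age_years) {
      reference_anthropometry(age_years)
    } else {
      interpolate_anthropometry(age_years)
    }
    body_weight <- body_weight %||% anth[["body_weight"]]
    height <- height %||% anth[["height"]]
  }
  stopifnot_scalar_positive(body_weight, "body_weight")
  stopifnot_scalar_positive(height, "height")

  co_rule <- config$cardiac_output_rule
  cardiac_output <- co_rule$coefficient_L_min * body_weight^co_rule$exponent
  comp <- data.frame(
    name = vapply(config$compartments, `[[`, character(1), "name"),
    volume = vapply(config$compartments, `[[`, numeric(1), "volume_fraction_bw") * body_weight,
    blood_flow = vapply(config$compartments, `[[`, numeric(1), "flow_fraction_co") * cardiac_output,
    partition_coefficient = vapply(config$compartments, `[[`, numeric(1), "partition_coefficient"),
    stringsAsFactors = FALSE
  )
  phys <- structure(
    list(
      age_years = age_years,
      body_weight = body_weight,
      height = height,
      compartments = comp,
      blood_volume = config$blood_volume_fraction_bw * body_weight,
      cardiac_output = cardiac_output,
      daily_urine_volume = daily_urine_volume(age_years, config)
    ),
    class = "child_physiology"
  )
  validate_physiology(phys)
}

#' @rdname build_physiology
#' @param physiology A `child_physiology` object to re-check.
#' @export
validate_physiology <- function(physiology) {
  comp <- physiology$compartments
  if (any(comp$volume <= 0) || any(comp$blood_flow <= 0) ||
      any(comp$partition_coefficient <= 0) || physiology$blood_volume <= 0 ||
      physiology$cardiac_output <= 0 || physiology$daily_urine_volume <= 0) {
    abort_config("all physiological volumes, flows and partition coefficients must be positive")
  }
  if (abs(sum(comp$blood_flow) - physiology$cardiac_output) >
      1e-9 * physiology$cardiac_output) {
    abort_config("compartment blood flows do not sum to cardiac output")
  }
  if (sum(comp$volume) + physiology$blood_volume > physiology$body_weight) {
    abort_config("total compartment plus blood volume exceeds body weight (1 kg/L)")
  }
  physiology
}

#' @export
print.child_physiology <- function(x, ...) {
  cat(sprintf("<child_physiology> age %g y, %.1f kg, %.0f cm\n",
              x$age_years, x$body_weight, x$height))
  cat(sprintf("  cardiac output %.3f L/min, blood volume %.2f L, urine %.2f L/day\n",
              x$cardiac_output, x$blood_volume, x$daily_urine_volume))
  print(x$compartments, row.names = FALSE)
  invisible(x)
}

#' Build the age-specific clearance set
#'
#' Plasma clearance is scaled allometrically from the configured adult
#' reference value and partitioned into bone and renal clearance with the
#' age-linear split of [clearance_fractions()].
#'
#' @inheritParams build_physiology
#' @param body_weight Body weight in kg.
#' @return An object of class `clearance_set` with fields `plasma_clearance`,
#'   `bone_fraction`, `renal_fraction`, `bone_clearance`, `renal_clearance`
#'   (all clearances in L/min).
#' @export
build_clearances <- function(age_years, body_weight, config = default_config()) {
  fr <- clearance_fractions(age_years)
  rc <- config$reference_clearance
  cl <- scale_plasma_clearance(body_weight, rc$value_L_min, rc$reference_bw_kg)
  structure(
    list(
      plasma_clearance = cl,
      bone_fraction = fr[["bone_fraction"]],
      renal_fraction = fr[["renal_fraction"]],
      bone_clearance = fr[["bone_fraction"]] * cl,
      renal_clearance = fr[["renal_fraction"]] * cl
    ),
    class = "clearance_set"
  )
}

#' @export
print.clearance_set <- function(x, ...) {
  cat(sprintf(
    "<clearance_set> plasma %.4g L/min = bone %.4g (%.1f%%) + renal %.4g (%.1f%%)\n",
    x$plasma_clearance, x$bone_clearance, 100 * x$bone_fraction,
    x$renal_clearance, 100 * x$renal_fraction))
  invisible(x)
}

#' Assemble a complete model bundle for one child
#'
#' A model bundle packages the physiology, clearances and configuration the
#' simulation engine needs, plus an optional urinary calibration factor (see
#' [compute_adjustment_factor()]). Predictions from a bundle carrying a
#' factor are calibrated by default.
#'
#' @inheritParams build_physiology
#' @param adjustment_factor Optional empirical urinary adjustment factor.
#' @return An object of class `model_bundle`.
#' @export
build_model_bundle <- function(age_years, config = default_config(),
                               body_weight = NULL, height = NULL,
                               adjustment_factor = NULL) {
  if (!is.null(adjustment_factor)) {
    stopifnot_scalar_positive(adjustment_factor, "adjustment_factor")
  }
  phys <- build_physiology(age_years, body_weight, height, config)
  structure(
    list(
      age_years = age_years,
      physiology = phys,
      clearances = build_clearances(age_years, phys$body_weight, config),
      config = config,
      adjustment_factor = adjustment_factor
    ),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> age %g y, %.1f kg%s\n", x$age_years,
              x$physiology$body_weight,
              if (is.null(x$adjustment_factor)) " (uncalibrated)"
              else sprintf(", calibrated (factor %.3f)", x$adjustment_factor)))
  invisible(x)
}
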