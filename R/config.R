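# Model configuration: versioned key-value rules for physiology, clearances
# and solver behaviour. All volume/flow rules are fractions (of body weight,
# of cardiac output) so the same config parameterizes any reference child.

.config_cache <- new.env(parent = emptyenv())

#' Load a model configuration file
#'
#' Reads a YAML configuration with the schema of the bundled
#' `config_default.yaml`: compartment volume/flow/partition rules, a cardiac
#' output rule, the reference adult plasma clearance used for allometric
#' scaling, daily urine volumes by age, and the bone/renal model switches.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list.
#' @seealso [default_config()], [validate_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("configuration file not found: %s", path))
  }
  validate_config(yaml::read_yaml(path))
}

#' Default model configuration
#'
#' The package's documented default parameterization (see the methods
#' vignette for the provenance of each value). The result is cached for the
#' session.
#'
#' @return A validated configuration list.
#' @export
default_config <- function() {
  if (is.null(.config_cache$default)) {
    path <- system.file("extdata", "config_default.yaml", package = "fluopbpk",
                        mustWork = TRUE)
    .config_cache$default <- load_config(path)
  }
  .config_cache$default
}

.required_compartments <- c("liver", "kidney", "bone", "rest_of_body")

#' Validate a model configuration
#'
#' Checks structural completeness (all four compartments with volume, flow
#' and partition rules), positivity, that flow fractions sum to one, and
#' that the model switches take known values. Errors name every missing key.
#'
#' @param config A configuration list.
#' @return The configuration, invisibly unchanged, for chaining.
#' @export
validate_config <- function(config) {
  top_needed <- c("reference_clearance", "cardiac_output_rule",
                  "blood_volume_fraction_bw", "compartments",
                  "daily_urine_volume_by_age", "bone_mode", "renal_driver")
  missing_top <- setdiff(top_needed, names(config))
  if (length(missing_top)) {
    abort_config(sprintf("configuration is missing keys: %s",
                         paste(missing_top, collapse = ", ")))
  }
  comp_names <- vapply(config$compartments, function(x) x$name %||% NA_character_,
                       character(1))
  missing_comp <- setdiff(.required_compartments, comp_names)
  if (length(missing_comp)) {
    abort_config(sprintf("configuration is missing compartments: %s",
                         paste(missing_comp, collapse = ", ")))
  }
  for (cmp in config$compartments) {
    fields <- c("volume_fraction_bw", "flow_fraction_co", "partition_coefficient")
    miss <- fields[!vapply(fields, function(f) is_scalar_number(cmp[[f]]) && cmp[[f]] > 0,
                           logical(1))]
    if (length(miss)) {
      abort_config(sprintf("compartment '%s' is missing or has non-positive: %s",
                           cmp$name, paste(miss, collapse = ", ")))
    }
  }
  ff <- vapply(config$compartments, function(x) x$flow_fraction_co, numeric(1))
  if (abs(sum(ff) - 1) > 1e-9) {
    abort_config(sprintf(
      "compartment flow fractions must sum to 1 (cardiac output); got %.6f",
      sum(ff)))
  }
  if (!is_scalar_number(config$blood_volume_fraction_bw) ||
      config$blood_volume_fraction_bw <= 0) {
    abort_config("blood_volume_fraction_bw must be a positive number")
  }
  rc <- config$reference_clearance
  if (!is_scalar_number(rc$value_L_min) || rc$value_L_min <= 0 ||
      !is_scalar_number(rc$reference_bw_kg) || rc$reference_bw_kg <= 0) {
    abort_config("reference_clearance needs positive value_L_min and reference_bw_kg")
  }
  co <- config$cardiac_output_rule
  if (!is_scalar_number(co$coefficient_L_min) || co$coefficient_L_min <= 0 ||
      !is_scalar_number(co$exponent)) {
    abort_config("cardiac_output_rule needs positive coefficient_L_min and an exponent")
  }
  uv <- config$daily_urine_volume_by_age
  ok <- length(uv) >= 1 && all(vapply(uv, function(x) {
    is_scalar_number(x$age_years) && is_scalar_number(x$volume_L_day) &&
      x$volume_L_day > 0
  }, logical(1)))
  if (!ok) abort_config("daily_urine_volume_by_age must list {age_years, volume_L_day > 0}")
  if (!config$bone_mode %in% c("equilibrating", "sink")) {
    abort_config("bone_mode must be 'equilibrating' or 'sink'")
  }
  if (!config$renal_driver %in% c("arterial", "kidney_exit")) {
    abort_config("renal_driver must be 'arterial' or 'kidney_exit'")
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Daily urine volume for a given age
#'
#' Linear interpolation between the configured age anchors (constant
#' extension outside their range). This value converts a daily excreted
#' amount (mg/day) into a urinary concentration (mg/L) and is flagged as
#' calibration-sensitive in the configuration.
#'
#' @param age_years Age in years.
#' @param config Model configuration, see [default_config()].
#' @return Daily urine volume in L/day.
#' @export
daily_urine_volume <- function(age_years, config = default_config()) {
  stopifnot_scalar_positive(age_years, "age_years")
  uv <- config$daily_urine_volume_by_age
  ages <- vapply(uv, function(x) x$age_years, numeric(1))
  vols <- vapply(uv, function(x) x$volume_L_day, numeric(1))
  if (length(ages) == 1L) return(vols)
  stats::approx(ages, vols, xout = age_years, rule = 2)$y
}
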