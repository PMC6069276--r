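# Model validation against published child cohorts: predict 24-h urinary
# fluoride for each study's intake profile, compare to the measured amounts,
# and derive the empirical urinary adjustment factor applied to all
# subsequent urinary predictions.

#' Read a validation-study table
#'
#' Tab-separated file with columns `age_years`, `n_children`, `intake_diet`,
#' `intake_toothpaste`, `intake_water`, `intake_supplement` (all intakes in
#' mg/day; supplements are fully absorbed fluoride tablets),
#' `measured_auf24` (measured 24-h urinary fluoride, mg/day) and `country`.
#'
#' @param path Path to the table.
#' @return A validated data frame of studies.
#' @export
read_validation_studies <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("validation table not found: %s", path))
  df <- utils::read.delim(path)
  needed <- c("age_years", "n_children", "intake_diet", "intake_toothpaste",
              "intake_water", "intake_supplement", "measured_auf24", "country")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    abort_config(sprintf("validation table missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  intakes <- df[c("intake_diet", "intake_toothpaste", "intake_water",
                  "intake_supplement")]
  if (any(as.matrix(intakes) < 0) || any(df$measured_auf24 <= 0)) {
    abort_config("intakes must be non-negative and measured_auf24 positive")
  }
  if (any(df$measured_auf24 >= rowSums(intakes))) {
    abort_config("measured urinary excretion cannot exceed total intake")
  }
  df
}

#' Bundled validation cohorts
#'
#' The six published child cohorts (ages 4-7; Venezuela, Chile, UK, Germany)
#' with estimated per-source fluoride intakes and measured 24-h urinary
#' fluoride, shipped as a plain-text fixture.
#'
#' @return Data frame of six studies.
#' @export
validation_studies <- function() {
  read_validation_studies(system.file("extdata", "validation_studies.tsv",
                                      package = "fluopbpk", mustWork = TRUE))
}

#' Absorbed daily dose of a validation study
#'
#' Applies the per-medium bioavailability defaults to the study's printed
#' intakes; supplements are fully absorbed.
#'
#' @param study One study (single-row data frame or list).
#' @return Absorbed dose in mg/day.
#' @export
study_absorbed_dose <- function(study) {
  f <- fluoride_bioavailability()
  study$intake_diet * f[["diet"]] +
    study$intake_toothpaste * f[["toothpaste"]] +
    study$intake_water * f[["water"]] +
    study$intake_supplement * 1.0
}

#' Predict the 24-h urinary fluoride of a validation study
#'
#' Builds the age-appropriate model (anthropometry linearly interpolated
#' between the reference children for intermediate ages) and returns the
#' uncalibrated steady-state 24-h urinary excretion for the study's absorbed
#' intake.
#'
#' @inheritParams study_absorbed_dose
#' @param config Model configuration.
#' @param use_cache Reuse memoised unit responses.
#' @return Predicted excreted amount in mg/day.
#' @export
predict_auf24 <- function(study, config = default_config(), use_cache = TRUE) {
  bundle <- build_model_bundle(study$age_years, config)
  predict_urinary_excretion(bundle, study_absorbed_dose(study),
                            calibrated = FALSE, use_cache = use_cache)
}

#' Empirical urinary adjustment factor from validation cohorts
#'
#' For each study the ratio measured/modeled 24-h urinary fluoride is
#' computed with the uncalibrated model; the adjustment factor is the
#' average of these ratios (arithmetic by default, geometric available).
#'
#' @param studies Data frame of validation studies, see
#'   [read_validation_studies()].
#' @param config Model configuration.
#' @param average `"arithmetic"` (default) or `"geometric"` mean of ratios.
#' @param use_cache Reuse memoised unit responses.
#' @return An object of class `calibration_result` with `per_study_ratio`
#'   and `adjustment_factor`.
#' @export
compute_adjustment_factor <- function(studies, config = default_config(),
                                      average = c("arithmetic", "geometric"),
                                      use_cache = TRUE) {
  average <- match.arg(average)
  if (nrow(studies) < 1) abort_config("at least one validation study is required")
  modeled <- vapply(seq_len(nrow(studies)), function(i) {
    predict_auf24(studies[i, , drop = FALSE], config, use_cache = use_cache)
  }, numeric(1))
  if (any(modeled <= 0)) {
    abort_numeric(sprintf(
      "calibration failure: non-positive modeled excretion for study %s",
      paste(which(modeled <= 0), collapse = ", ")))
  }
  ratios <- studies$measured_auf24 / modeled
  factor <- if (average == "arithmetic") mean(ratios) else exp(mean(log(ratios)))
  structure(
    list(per_study_ratio = ratios,
         modeled_auf24 = modeled,
         measured_auf24 = studies$measured_auf24,
         country = studies$country,
         age_years = studies$age_years,
         average = average,
         adjustment_factor = factor),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> adjustment factor %.4f (%s mean of %d ratios)\n",
              x$adjustment_factor, x$average, length(x$per_study_ratio)))
  print(data.frame(country = x$country, age_years = x$age_years,
                   measured = x$measured_auf24,
                   modeled = round(x$modeled_auf24, 4),
                   ratio = round(x$per_study_ratio, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Apply the empirical urinary adjustment factor
#'
#' Multiplies a urinary prediction (excreted amount or concentration) by the
#' calibration factor. Outputs are flagged with a `calibrated` attribute and
#' applying the factor twice is an error.
#'
#' @param prediction Urinary prediction (mg/day or mg/L).
#' @param factor Positive adjustment factor, or a `calibration_result`.
#' @return The adjusted prediction with attribute `calibrated = TRUE`.
#' @export
apply_adjustment <- function(prediction, factor) {
  if (inherits(factor, "calibration_result")) factor <- factor$adjustment_factor
  stopifnot_scalar_positive(factor, "factor")
  if (isTRUE(attr(prediction, "calibrated"))) {
    abort_config("prediction is already calibrated; refusing to apply the factor twice")
  }
  out <- as.numeric(prediction) * factor
  attr(out, "calibrated") <- TRUE
  out
}

#' Build a calibrated model bundle
#'
#' Convenience wrapper: computes the adjustment factor from the bundled
#' validation cohorts (or supplied ones) and attaches it to a model bundle
#' for the requested age.
#'
#' @inheritParams build_model_bundle
#' @param studies Validation studies used to derive the factor.
#' @return A calibrated `model_bundle`.
#' @export
calibrated_bundle <- function(age_years, config = default_config(),
                              studies = validation_studies()) {
  cal <- compute_adjustment_factor(studies, config)
  build_model_bundle(age_years, config,
                     adjustment_factor = cal$adjustment_factor)
}
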