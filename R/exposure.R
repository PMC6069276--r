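# Aggregate exposure: per-source intakes, bioavailability, absorbed total
# daily fluoride intake (TDFI), equivalent population water concentrations
# and per-source contribution shares. All internal dose bookkeeping is in
# ug/kg/day; conversion to the engine's mg/day happens once at the boundary.

.media <- c("water", "diet", "toothpaste", "soil", "air")

#' Default source-specific oral bioavailability fractions
#'
#' Fraction of an ingested/inhaled amount reaching systemic circulation:
#' water 0.83, air 1.0, toothpaste 1.0, diet 0.40 and soil 0.40 (soil is
#' assigned the dietary value as the factors influencing its bioavailability
#' are similar).
#'
#' @return Named numeric vector keyed by medium.
#' @export
fluoride_bioavailability <- function() {
  c(water = 0.83, diet = 0.40, toothpaste = 1.0, soil = 0.40, air = 1.0)
}

#' Define one exposure source
#'
#' Mass-rate sources (`diet`, `toothpaste`, `soil`, `air`) are specified as
#' intakes in ug/kg/day; the `water` source as a consumption volume (L/day)
#' with a concentration (mg/L).
#'
#' @param medium One of `"water"`, `"diet"`, `"toothpaste"`, `"soil"`, `"air"`.
#' @param intake_ugkgday Intake for mass-rate sources (ug/kg/day).
#' @param volume_L_day,concentration_mg_L Water consumption volume and
#'   fluoride concentration.
#' @param bioavailability Optional override of the medium default, in (0, 1].
#' @return An object of class `exposure_source`.
#' @export
exposure_source <- function(medium, intake_ugkgday = NULL, volume_L_day = NULL,
                            concentration_mg_L = NULL, bioavailability = NULL) {
  medium <- match.arg(medium, .media)
  f <- bioavailability %||% fluoride_bioavailability()[[medium]]
  if (!is_scalar_number(f) || f <= 0 || f > 1) {
    abort_config("bioavailability must lie in (0, 1]")
  }
  if (medium == "water") {
    if (is.null(volume_L_day)) {
      abort_config("water source requires volume_L_day")
    }
    if (!is_scalar_number(volume_L_day) || volume_L_day < 0) {
      abort_domain("volume_L_day must be non-negative")
    }
    if (!is.null(concentration_mg_L) &&
        (!is_scalar_number(concentration_mg_L) || concentration_mg_L < 0)) {
      abort_domain("concentration_mg_L must be non-negative")
    }
  } else {
    if (is.null(intake_ugkgday) || !is_scalar_number(intake_ugkgday) ||
        intake_ugkgday < 0) {
      abort_domain(sprintf("%s source requires a non-negative intake_ugkgday", medium))
    }
  }
  structure(
    list(medium = medium, intake_ugkgday = intake_ugkgday,
         volume_L_day = volume_L_day, concentration_mg_L = concentration_mg_L,
         bioavailability = f),
    class = "exposure_source"
  )
}

#' Assemble an exposure scenario for one child
#'
#' @param label Scenario label used in reports.
#' @param age_years,body_weight Child the scenario applies to.
#' @param sources List of [exposure_source()] objects; exactly one water
#'   source, each medium at most once.
#' @param notes Free-text annotation.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(label, age_years, body_weight, sources, notes = "") {
  stopifnot_scalar_positive(age_years, "age_years")
  stopifnot_scalar_positive(body_weight, "body_weight")
  media <- vapply(sources, function(s) s$medium, character(1))
  if (anyDuplicated(media)) {
    abort_config("each exposure medium may appear at most once in a scenario")
  }
  if (sum(media == "water") != 1) {
    abort_config("a scenario requires exactly one water source")
  }
  water <- sources[[which(media == "water")]]
  structure(
    list(label = label, age_years = age_years, body_weight = body_weight,
         sources = stats::setNames(sources, media),
         water_concentration = water$concentration_mg_L, notes = notes),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("<exposure_scenario> '%s', age %g y (%g kg), water %.3g mg/L\n",
              x$label, x$age_years, x$body_weight,
              x$water_concentration %||% NA_real_))
  cat(sprintf("  sources: %s\n", paste(names(x$sources), collapse = ", ")))
  invisible(x)
}

#' Population-equivalent water fluoride concentration
#'
#' Coverage-weighted mean of the fluoridated and background concentrations:
#' `coverage * fluoridated + (1 - coverage) * background`.
#'
#' @param coverage Fraction of the population on fluoridated water, in \[0, 1\].
#' @param fluoridated_conc,background_conc Concentrations in mg/L.
#' @return Equivalent concentration in mg/L.
#' @examples
#' equivalent_water_concentration(0.70, 0.7, 0.05) # 0.505, reported as 0.5
#' @export
equivalent_water_concentration <- function(coverage, fluoridated_conc,
                                           background_conc) {
  if (!is_scalar_number(coverage) || coverage < 0 || coverage > 1) {
    abort_domain("coverage must lie in [0, 1]")
  }
  if (!is_scalar_number(fluoridated_conc) || fluoridated_conc < 0 ||
      !is_scalar_number(background_conc) || background_conc < 0) {
    abort_domain("concentrations must be non-negative")
  }
  coverage * fluoridated_conc + (1 - coverage) * background_conc
}

# bundled per-age intake parameters, cached after first read
.exposure_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "exposure_parameters.tsv",
                          package = "fluopbpk", mustWork = TRUE)
      cache <<- utils::read.delim(path)
    }
    cache
  }
})

#' Bundled age-specific exposure parameters
#'
#' The per-age fixed exposure parameters (body size plus per-source fluoride
#' intakes and daily water consumption) for the 4- and 8-year-old reference
#' children.
#'
#' @param age_years 4 or 8.
#' @return One-row data frame.
#' @export
age_exposure_parameters <- function(age_years) {
  tab <- .exposure_params()
  i <- match(age_years, tab$age_years)
  if (is.na(i)) {
    abort_config(sprintf("no bundled exposure parameters for age %s", age_years))
  }
  tab[i, , drop = FALSE]
}

.presets <- c("fluoridated-tap", "ontario-s1", "quebec-s2", "quebec-s3")

#' Named exposure-scenario presets
#'
#' Builds the study's exposure scenarios for a reference child:
#' \describe{
#'   \item{`fluoridated-tap`}{all sources, tap water at 0.7 mg/L (used for
#'     the drinking-water contribution analysis).}
#'   \item{`ontario-s1`}{scenario 1: all sources, water at the Ontario
#'     population-equivalent concentration (70% coverage at 0.7 mg/L, 30%
#'     at the 0.05 mg/L detection limit, i.e. 0.505 mg/L).}
#'   \item{`quebec-s2`}{scenario 2: all sources, water at 0.06 mg/L (the
#'     published Quebec population-equivalent).}
#'   \item{`quebec-s3`}{scenario 3: scenario 2 with the dietary source
#'     removed, all else identical.}
#' }
#'
#' @param name Preset name.
#' @param age_years 4 or 8.
#' @return An [exposure_scenario()] object.
#' @export
scenario_preset <- function(name, age_years) {
  if (!is.character(name) || length(name) != 1L || !name %in% .presets) {
    abort_config(sprintf("unknown scenario preset '%s'; valid presets: %s",
                         paste(name, collapse = ","),
                         paste(.presets, collapse = ", ")))
  }
  row <- age_exposure_parameters(age_years)
  water_conc <- switch(name,
    "fluoridated-tap" = 0.7,
    "ontario-s1" = equivalent_water_concentration(0.70, 0.7, 0.05),
    "quebec-s2" = 0.06,
    "quebec-s3" = 0.06
  )
  sources <- list(
    exposure_source("toothpaste", intake_ugkgday = row$toothpaste_ugkgday),
    exposure_source("diet", intake_ugkgday = row$diet_ugkgday),
    exposure_source("soil", intake_ugkgday = row$soil_ugkgday),
    exposure_source("air", intake_ugkgday = row$air_ugkgday),
    exposure_source("water", volume_L_day = row$water_L_day,
                    concentration_mg_L = water_conc)
  )
  if (name == "quebec-s3") {
    sources <- Filter(function(s) s$medium != "diet", sources)
  }
  exposure_scenario(
    label = name, age_years = age_years, body_weight = row$body_weight_kg,
    sources = sources,
    notes = sprintf("preset '%s', water %.3g mg/L", name, water_conc)
  )
}

#' Absorbed intake from one source
#'
#' Applies the source's bioavailability: mass-rate sources are
#' `intake * bioavailability`; the water source is
#' `volume * concentration / body_weight * bioavailability` with units
#' reconciled to ug/kg/day.
#'
#' @param source An [exposure_source()].
#' @param body_weight Body weight in kg.
#' @return Absorbed intake in ug/kg/day.
#' @export
absorbed_intake <- function(source, body_weight) {
  stopifnot_scalar_positive(body_weight, "body_weight")
  if (source$medium == "water") {
    if (is.null(source$concentration_mg_L)) {
      abort_config("water source is missing its fluoride concentration")
    }
    source$volume_L_day * source$concentration_mg_L * 1000 / body_weight *
      source$bioavailability
  } else {
    source$intake_ugkgday * source$bioavailability
  }
}

#' Total absorbed daily fluoride intake of a scenario
#'
#' @param scenario An [exposure_scenario()].
#' @return Absorbed TDFI in ug/kg/day.
#' @export
total_absorbed_tdfi <- function(scenario) {
  sum(vapply(scenario$sources, absorbed_intake, numeric(1),
             body_weight = scenario$body_weight))
}

#' Absorbed daily dose of a scenario in engine units
#'
#' @param scenario An [exposure_scenario()].
#' @return Absorbed dose in mg/day for the scenario's child.
#' @export
scenario_daily_dose <- function(scenario) {
  total_absorbed_tdfi(scenario) * scenario$body_weight / 1000
}

#' Per-source contributions to the absorbed intake
#'
#' Fractional share of each exposure medium in the total absorbed daily
#' fluoride intake. Because the kinetic model is linear in dose, these
#' shares equal the shares of steady-state urinary excretion attributable
#' to each source; `method = "pbpk"` verifies this by simulating each
#' source in isolation.
#'
#' @param scenario An [exposure_scenario()] with positive total intake.
#' @param method `"intake"` (arithmetic shares) or `"pbpk"` (per-source
#'   steady-state simulation shares).
#' @param config Model configuration for `method = "pbpk"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
source_contributions <- function(scenario, method = c("intake", "pbpk"),
                                 config = default_config()) {
  method <- match.arg(method)
  absorbed <- vapply(scenario$sources, absorbed_intake, numeric(1),
                     body_weight = scenario$body_weight)
  if (sum(absorbed) <= 0) {
    abort_domain("source contributions are undefined for a zero total intake")
  }
  if (method == "intake") {
    return(absorbed / sum(absorbed))
  }
  bundle <- build_model_bundle(scenario$age_years, config,
                               body_weight = scenario$body_weight)
  excreted <- vapply(absorbed, function(a) {
    predict_urinary_excretion(bundle, a * scenario$body_weight / 1000,
                              calibrated = FALSE, use_cache = FALSE)
  }, numeric(1))
  excreted / sum(excreted)
}

#' Convert an ingested intake to an absorbed dose
#'
#' @param intake Ingested intake in mg/kg/day.
#' @param aggregate_bioavailability Aggregate oral bioavailability fraction
#'   in (0, 1]; the default 0.8 is the water/diet-weighted aggregate used
#'   for intake-to-absorbed conversions of guidance values.
#' @return Absorbed dose in mg/kg/day (unrounded).
#' @examples
#' intake_to_absorbed(0.05) # suggested optimal absorbed dose, 0.04
#' intake_to_absorbed(0.10) # absorbed Canadian tolerable daily intake, 0.08
#' @export
intake_to_absorbed <- function(intake, aggregate_bioavailability = 0.8) {
  if (!is_scalar_number(intake) || intake < 0) {
    abort_domain("intake must be a single non-negative number")
  }
  if (!is_scalar_number(aggregate_bioavailability) ||
      aggregate_bioavailability <= 0 || aggregate_bioavailability > 1) {
    abort_domain("aggregate_bioavailability must lie in (0, 1]")
  }
  intake * aggregate_bioavailability
}

#' Convert an absorbed per-kg intake to the hepatic infusion rate
#'
#' @param total_absorbed Absorbed TDFI in ug/kg/day.
#' @param body_weight Body weight in kg.
#' @return Infusion rate in mg/min.
#' @export
to_infusion_rate <- function(total_absorbed, body_weight) {
  if (!is_scalar_number(total_absorbed) || total_absorbed < 0 ||
      !is_scalar_number(body_weight) || body_weight < 0) {
    abort_domain("inputs must be non-negative numbers")
  }
  total_absorbed * body_weight / 1000 / 1440
}
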