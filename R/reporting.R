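# Report generation mirroring the study's result tables, plus a thin
# command-line dispatcher over the package functions.

.preset_region <- c("fluoridated-tap" = "Ontario", "ontario-s1" = "Ontario",
                    "quebec-s2" = "Quebec", "quebec-s3" = "Quebec")

#' Scenario report: modeled urinary concentrations vs. biomonitoring
#'
#' Simulates each scenario preset to steady state with the calibrated
#' model and tabulates the modeled urinary fluoride concentration, the
#' matching biomonitoring geometric mean, and their ratio.
#'
#' @param ages Ages to model.
#' @param presets Scenario presets to run.
#' @param config Model configuration.
#' @param chms Biomonitoring records used for the comparison column.
#' @return Data frame with one row per (preset, age).
#' @export
report_scenarios <- function(ages = c(4, 8),
                             presets = c("ontario-s1", "quebec-s2", "quebec-s3"),
                             config = default_config(),
                             chms = chms_biomonitoring()) {
  cal <- compute_adjustment_factor(validation_studies(), config)
  rows <- list()
  for (preset in presets) {
    for (age in ages) {
      scn <- scenario_preset(preset, age)
      bundle <- build_model_bundle(age, config,
                                   adjustment_factor = cal$adjustment_factor)
      excretion <- predict_urinary_excretion(bundle, scenario_daily_dose(scn))
      conc <- urinary_concentration(excretion,
                                    bundle$physiology$daily_urine_volume)
      region <- .preset_region[[preset]]
      hit <- chms$region == region & chms$age_group_median == age &
        chms$statistic == "geometric_mean"
      chms_conc <- if (any(hit)) chms$urinary_concentration[hit][1] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = preset, region = region, age_years = age,
        water_mg_L = scn$water_concentration,
        absorbed_tdfi_ugkgday = total_absorbed_tdfi(scn),
        dose_mg_day = scenario_daily_dose(scn),
        excretion_mg_day = as.numeric(excretion),
        modeled_conc_mg_L = as.numeric(conc),
        chms_conc_mg_L = chms_conc,
        ratio = as.numeric(conc) / chms_conc,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Source-contribution report
#'
#' Per-source absorbed intakes, modeled steady-state urinary excretion and
#' fractional shares of the total daily fluoride intake for one scenario.
#'
#' @param preset Scenario preset (default `fluoridated-tap`, the
#'   drinking-water contribution analysis at 0.7 mg/L).
#' @param age_years Reference child age.
#' @param config Model configuration.
#' @param method Share computation passed to [source_contributions()].
#' @return Data frame with one row per source plus the share column.
#' @export
report_contributions <- function(preset = "fluoridated-tap", age_years = 4,
                                 config = default_config(),
                                 method = "intake") {
  scn <- scenario_preset(preset, age_years)
  cal <- compute_adjustment_factor(validation_studies(), config)
  bundle <- build_model_bundle(age_years, config,
                               adjustment_factor = cal$adjustment_factor)
  absorbed <- vapply(scn$sources, absorbed_intake, numeric(1),
                     body_weight = scn$body_weight)
  shares <- source_contributions(scn, method = method, config = config)
  excreted <- vapply(absorbed, function(a) {
    as.numeric(predict_urinary_excretion(bundle, a * scn$body_weight / 1000))
  }, numeric(1))
  data.frame(
    medium = names(scn$sources),
    absorbed_ugkgday = unname(absorbed),
    absorbed_mg_day = unname(absorbed) * scn$body_weight / 1000,
    excreted_mg_day = unname(excreted),
    share = unname(shares[names(scn$sources)]),
    stringsAsFactors = FALSE
  )
}

#' Reverse-dosimetry report
#'
#' @inheritParams invert_biomonitoring
#' @return See [invert_biomonitoring()].
#' @export
report_inversions <- function(records = chms_biomonitoring(),
                              config = default_config()) {
  invert_biomonitoring(records, config)
}

#' Sensitivity report
#'
#' @inheritParams screen_parameters
#' @return See [screen_parameters()].
#' @export
report_sensitivity <- function(threshold = 0.05, ages = c(4, 8),
                               config = default_config()) {
  screen_parameters(threshold = threshold, ages = ages, config = config)
}

#' Write a report as delimiter-separated values and JSON
#'
#' @param df Report data frame.
#' @param dir Output directory (created if missing).
#' @param name Base file name without extension.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(df, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  json <- file.path(dir, paste0(name, ".json"))
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Write a machine-readable provenance record
#'
#' Records the package version, a configuration digest, the full
#' configuration and the seed, so a report directory is self-describing.
#'
#' @param dir Output directory.
#' @param config Model configuration used for the run.
#' @param seed Seed used for the run (if any).
#' @return Invisibly, the path written.
#' @export
write_provenance <- function(dir, config = default_config(), seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(config, tmp)
  rec <- list(
    package = "fluopbpk",
    version = as.character(utils::packageVersion("fluopbpk")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    config = config
  )
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.cli_flag <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) abort_config(sprintf("flag %s needs a value", flag))
  args[i[1] + 1L]
}

#' Command-line dispatcher
#'
#' Thin shell interface over the reporting functions, used by the installed
#' `inst/cli/fluopbpk` script. Subcommands: `simulate`, `validate`,
#' `invert`, `contributions`, `sensitivity`, `fixtures`. Common flags:
#' `--age`, `--preset`, `--file`, `--threshold`, `--config`, `--seed`,
#' `--out DIR` (default `fluopbpk-output`), `--quiet`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, an exit status: 0 success, 2 configuration error,
#'   3 numerical failure.
#' @export
fluopbpk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      abort_config(paste("usage: fluopbpk <simulate|validate|invert|",
                         "contributions|sensitivity|fixtures> [flags]"))
    }
    cmd <- args[1]
    out_dir <- .cli_flag(args, "--out", "fluopbpk-output")
    quiet <- "--quiet" %in% args
    seed <- .cli_flag(args, "--seed")
    if (!is.null(seed)) set.seed(as.integer(seed))
    cfg_path <- .cli_flag(args, "--config")
    config <- if (is.null(cfg_path)) default_config() else load_config(cfg_path)
    age <- as.numeric(.cli_flag(args, "--age", "4"))
    preset <- .cli_flag(args, "--preset", "fluoridated-tap")
    threshold <- as.numeric(.cli_flag(args, "--threshold", "0.05"))

    report <- switch(cmd,
      simulate = report_scenarios(config = config),
      validate = {
        cal <- compute_adjustment_factor(validation_studies(), config)
        data.frame(country = cal$country, age_years = cal$age_years,
                   measured = cal$measured_auf24, modeled = cal$modeled_auf24,
                   ratio = cal$per_study_ratio,
                   adjustment_factor = cal$adjustment_factor)
      },
      invert = {
        file <- .cli_flag(args, "--file")
        recs <- if (is.null(file)) chms_biomonitoring() else read_biomonitoring(file)
        report_inversions(recs, config)
      },
      contributions = report_contributions(preset, age, config),
      sensitivity = report_sensitivity(threshold, config = config),
      fixtures = {
        fx <- bundled_fixtures()
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        for (nm in names(fx)) {
          utils::write.table(fx[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
        data.frame(fixture = names(fx),
                   rows = vapply(fx, nrow, integer(1)))
      },
      abort_config(sprintf(
        "unknown subcommand '%s'; valid: simulate, validate, invert, contributions, sensitivity, fixtures",
        cmd))
    )
    write_report(report, out_dir, cmd)
    write_provenance(out_dir, config,
                     seed = if (is.null(seed)) NULL else as.integer(seed))
    if (!quiet) print(report)
    0L
  },
  fluopbpk_config_error = function(e) {
    message("configuration error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}
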