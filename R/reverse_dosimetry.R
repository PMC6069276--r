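# Reverse dosimetry: invert urinary biomonitoring concentrations into
# absorbed daily fluoride doses through the calibrated forward model, and
# compare the recovered doses to absorbed guidance values.

#' Read a biomonitoring table
#'
#' Tab-separated file with columns `region`, `age_group_median`, `statistic`
#' (`geometric_mean` or `p95`) and `urinary_concentration` (mg/L).
#'
#' @param path Path to the table.
#' @return A validated data frame of biomonitoring records.
#' @export
read_biomonitoring <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("biomonitoring table not found: %s", path))
  df <- utils::read.delim(path)
  needed <- c("region", "age_group_median", "statistic", "urinary_concentration")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    abort_config(sprintf("biomonitoring table missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(df$urinary_concentration) | df$urinary_concentration <= 0)
  if (length(bad)) {
    abort_config(sprintf("non-positive urinary concentration in row(s): %s",
                         paste(bad, collapse = ", ")))
  }
  df
}

#' Bundled provincial urinary fluoride biomonitoring records
#'
#' Geometric-mean spot-urine fluoride concentrations for 4- and 8-year-old
#' children in two provinces with very different drinking-water fluoridation
#' coverage, shipped as a plain-text fixture.
#'
#' @return Data frame of biomonitoring records.
#' @export
chms_biomonitoring <- function() {
  read_biomonitoring(system.file("extdata", "chms_urinary_fluoride.tsv",
                                 package = "fluopbpk", mustWork = TRUE))
}

#' Convert a urinary concentration to a daily excreted amount
#'
#' @param concentration Urinary fluoride concentration in mg/L (positive).
#' @param daily_urine_volume Daily urine volume in L/day (positive).
#' @return Excreted amount in mg/day.
#' @export
conc_to_daily_amount <- function(concentration, daily_urine_volume) {
  stopifnot_scalar_positive(concentration, "concentration")
  stopifnot_scalar_positive(daily_urine_volume, "daily_urine_volume")
  concentration * daily_urine_volume
}

#' Invert a daily urinary amount into an absorbed dose
#'
#' Solves `f(d) = predicted_excretion(d) - target = 0` for the absorbed
#' total daily fluoride intake `d` (mg/kg/day) with a bracketed scalar root
#' finder, mirroring a single-unknown solver with the positivity constraint
#' `d > 0`. The forward prediction uses the bundle's calibration factor when
#' present. The bracket is expanded geometrically if it does not straddle
#' the root.
#'
#' @param target_daily_amount Target 24-h excreted amount in mg/day.
#' @param bundle A [build_model_bundle()] object (normally calibrated, see
#'   [calibrated_bundle()]).
#' @param bracket Initial search interval in mg/kg/day; lower bound > 0.
#' @param tol Residual tolerance in mg/day.
#' @param calibrated Use the calibrated forward model (default: whenever the
#'   bundle carries a factor).
#' @param use_cache Reuse memoised unit responses in the forward model.
#' @param max_expand Maximum number of tenfold bracket expansions.
#' @return An object of class `inversion_result` with fields
#'   `absorbed_tdfi` (mg/kg/day), `converged`, `residual` (mg/day) and
#'   `iterations`.
#' @export
invert_absorbed_dose <- function(target_daily_amount, bundle,
                                 bracket = c(1e-6, 1.0), tol = 1e-10,
                                 calibrated = !is.null(bundle$adjustment_factor),
                                 use_cache = TRUE, max_expand = 6L) {
  stopifnot_scalar_positive(target_daily_amount, "target_daily_amount")
  if (length(bracket) != 2L || bracket[1] <= 0 || bracket[2] <= bracket[1]) {
    abort_domain("bracket must be an increasing positive interval in mg/kg/day")
  }
  bw <- bundle$physiology$body_weight
  f <- function(d) {
    predict_urinary_excretion(bundle, d * bw, calibrated = calibrated,
                              use_cache = use_cache) - target_daily_amount
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  expansions <- 0L
  while (flo * fhi > 0 && expansions < max_expand) {
    if (flo > 0) { lo <- lo / 10; flo <- f(lo) } else { hi <- hi * 10; fhi <- f(hi) }
    expansions <- expansions + 1L
  }
  if (flo * fhi > 0) {
    abort_numeric(sprintf(
      "target %.4g mg/day cannot be bracketed in [%.3g, %.3g] mg/kg/day",
      target_daily_amount, lo, hi))
  }
  root <- stats::uniroot(f, lower = lo, upper = hi,
                         f.lower = flo, f.upper = fhi,
                         tol = .Machine$double.eps^0.75)
  residual <- f(root$root)
  # the residual cannot be driven below the forward solver's relative
  # accuracy (rtol 1e-8), so the tolerance is floored there
  tol_eff <- max(tol, 2e-8 * target_daily_amount)
  converged <- is.finite(residual) && abs(residual) <= tol_eff
  if (!converged) {
    abort_numeric(sprintf(
      "inversion did not converge: residual %.3g mg/day exceeds tolerance %.3g",
      residual, tol_eff))
  }
  structure(
    list(absorbed_tdfi = root$root, converged = converged,
         residual = residual, iterations = root$iter,
         target_daily_amount = target_daily_amount,
         calibrated = calibrated),
    class = "inversion_result"
  )
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "<inversion_result> absorbed TDFI %.4g mg/kg/day (residual %.2g mg/day, %d iterations)\n",
    x$absorbed_tdfi, x$residual, x$iterations))
  invisible(x)
}

#' Classify an absorbed dose against guidance thresholds
#'
#' Compares an absorbed daily dose to the suggested optimal absorbed dose
#' and to absorbed tolerable daily intakes (TDIs), without rounding before
#' the comparison.
#'
#' @param absorbed_tdfi Absorbed dose in mg/kg/day.
#' @param thresholds Named positive thresholds in mg/kg/day; defaults are
#'   the optimal absorbed dose 0.04, the absorbed Canadian TDI 0.08 and the
#'   absorbed Australia/New Zealand TDI 0.16.
#' @return Data frame with one row per threshold and a `status` column
#'   (`"not reached"`, `"reached"`, `"exceeded"`); a one-line `summary`
#'   attribute describes the classification.
#' @export
compare_to_thresholds <- function(absorbed_tdfi,
                                  thresholds = c(optimal = 0.04,
                                                 tdi_canada_absorbed = 0.08,
                                                 tdi_aunz_absorbed = 0.16)) {
  stopifnot_scalar_positive(absorbed_tdfi, "absorbed_tdfi")
  if (any(thresholds <= 0)) abort_domain("thresholds must be positive")
  status <- ifelse(absorbed_tdfi > thresholds, "exceeded",
                   ifelse(absorbed_tdfi == thresholds, "reached", "not reached"))
  out <- data.frame(threshold = names(thresholds), value = unname(thresholds),
                    status = unname(status), stringsAsFactors = FALSE)
  attr(out, "summary") <- paste(
    sprintf("%s %s (%.3g)", out$threshold, out$status, out$value),
    collapse = "; ")
  out
}

#' Invert a table of biomonitoring records
#'
#' Runs the full reverse-dosimetry chain for each record: concentration to
#' daily amount via the configured age-specific urine volume, solver-based
#' inversion through the calibrated model, and threshold classification.
#'
#' @param records Data frame of biomonitoring records, see
#'   [read_biomonitoring()]; defaults to the bundled provincial values.
#' @param config Model configuration.
#' @param studies Validation cohorts used to derive the calibration factor.
#' @return Data frame with one row per record: absorbed dose, convergence
#'   diagnostics and threshold classification.
#' @export
invert_biomonitoring <- function(records = chms_biomonitoring(),
                                 config = default_config(),
                                 studies = validation_studies()) {
  if (nrow(records) == 0) {
    warning("empty biomonitoring table; returning empty report", call. = FALSE)
    return(data.frame())
  }
  cal <- compute_adjustment_factor(studies, config)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    bundle <- build_model_bundle(rec$age_group_median, config,
                                 adjustment_factor = cal$adjustment_factor)
    target <- conc_to_daily_amount(rec$urinary_concentration,
                                   bundle$physiology$daily_urine_volume)
    inv <- invert_absorbed_dose(target, bundle)
    cls <- compare_to_thresholds(inv$absorbed_tdfi)
    data.frame(
      region = rec$region, age_years = rec$age_group_median,
      statistic = rec$statistic,
      urinary_concentration = rec$urinary_concentration,
      daily_amount_mg = target,
      absorbed_tdfi = inv$absorbed_tdfi,
      residual = inv$residual,
      classification = attr(cls, "summary"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
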