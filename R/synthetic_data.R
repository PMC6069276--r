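# Synthetic inputs for testing the full pipeline without downloads:
# lognormal spot-urine concentration samples with prescribed geometric
# statistics, and validation cohorts with known ground truth for
# parameter-recovery tests; plus integrity-checked access to the bundled
# plain-text fixtures.

#' Specification of a lognormal spot-urine concentration distribution
#'
#' Biomonitoring surveys report urinary fluoride on the multiplicative
#' scale; a lognormal with geometric mean `gm` and geometric standard
#' deviation `gsd` has its 95th percentile at `gm * gsd^qnorm(0.95)`
#' (closed form, exposed as `$p95`).
#'
#' @param geometric_mean Geometric mean in mg/L (positive).
#' @param geometric_sd Geometric standard deviation (> 1).
#' @param n Sample size.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `lognormal_spec`.
#' @export
lognormal_spec <- function(geometric_mean, geometric_sd = 2.0, n = 1000L,
                           seed = 1L) {
  stopifnot_scalar_positive(geometric_mean, "geometric_mean")
  if (!is_scalar_number(geometric_sd) || geometric_sd <= 1) {
    abort_domain("geometric_sd must be > 1")
  }
  if (!is_scalar_number(n) || n < 1) abort_domain("n must be a positive count")
  structure(
    list(geometric_mean = geometric_mean, geometric_sd = geometric_sd,
         n = as.integer(n), seed = as.integer(seed),
         p95 = geometric_mean * geometric_sd^stats::qnorm(0.95)),
    class = "lognormal_spec"
  )
}

#' Sample synthetic spot-urine fluoride concentrations
#'
#' Draws `n` lognormal concentrations with the specified geometric mean and
#' geometric standard deviation, returned as biomonitoring records.
#' Deterministic given the specification's seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [lognormal_spec()].
#' @param region,age_group_median,statistic Labels attached to the records.
#' @return Data frame of biomonitoring records with one row per sample.
#' @export
sample_urinary_concentrations <- function(spec, region = "synthetic",
                                          age_group_median = 4,
                                          statistic = "sample") {
  stopifnot(inherits(spec, "lognormal_spec"))
  x <- with_seed(spec$seed,
                 stats::rlnorm(spec$n, meanlog = log(spec$geometric_mean),
                               sdlog = log(spec$geometric_sd)))
  data.frame(
    region = region, age_group_median = age_group_median,
    statistic = statistic, urinary_concentration = x,
    stringsAsFactors = FALSE
  )
}

#' Generate a validation cohort with known ground truth
#'
#' Emulates the validation table: `n_studies` studies with ages drawn from
#' 4-8 years and per-source intakes in the ranges spanned by the published
#' cohorts. Each study's "measured" 24-h urinary fluoride is the
#' uncalibrated model prediction times a known multiplicative bias and
#' lognormal measurement noise (geometric mean 1, geometric SD
#' `noise_gsd`), so [compute_adjustment_factor()] should recover the bias.
#'
#' @param true_bias Known multiplicative bias (> 0).
#' @param noise_gsd Geometric SD of the measurement noise; 1 = noise-free.
#' @param n_studies Number of studies to generate.
#' @param seed Integer seed.
#' @param config Model configuration used for the underlying predictions.
#' @return An object of class `synthetic_cohort`: list with `studies` (a
#'   validation-study data frame), `true_bias`, `noise_gsd` and `seed`.
#' @export
make_validation_cohort <- function(true_bias, noise_gsd = 1.3,
                                   n_studies = 200L, seed = 7L,
                                   config = default_config()) {
  stopifnot_scalar_positive(true_bias, "true_bias")
  if (!is_scalar_number(noise_gsd) || noise_gsd < 1) {
    abort_domain("noise_gsd must be >= 1")
  }
  draws <- with_seed(seed, {
    list(
      age = sample(4:8, n_studies, replace = TRUE),
      diet = stats::runif(n_studies, 0.05, 0.60),
      toothpaste = stats::runif(n_studies, 0.20, 1.20),
      water = stats::runif(n_studies, 0.04, 0.45),
      supplement = stats::rbinom(n_studies, 1, 0.2) *
        stats::runif(n_studies, 0.20, 0.50),
      noise = if (noise_gsd > 1) {
        stats::rlnorm(n_studies, 0, log(noise_gsd))
      } else rep(1, n_studies)
    )
  })
  studies <- data.frame(
    age_years = draws$age, n_children = 20L,
    intake_diet = draws$diet, intake_toothpaste = draws$toothpaste,
    intake_water = draws$water, intake_supplement = draws$supplement,
    measured_auf24 = NA_real_,
    country = sprintf("synthetic-%03d", seq_len(n_studies)),
    stringsAsFactors = FALSE
  )
  modeled <- vapply(seq_len(n_studies), function(i) {
    predict_auf24(studies[i, , drop = FALSE], config)
  }, numeric(1))
  studies$measured_auf24 <- true_bias * draws$noise * modeled
  structure(
    list(true_bias = true_bias, noise_gsd = noise_gsd, seed = seed,
         studies = studies),
    class = "synthetic_cohort"
  )
}

.fixture_md5 <- c(
  validation_studies.tsv = "d73754d81dda7ab4ed09c72038e6a9bc",
  exposure_parameters.tsv = "4057c5b9ae42bd3f284b92ead6ff0307",
  chms_urinary_fluoride.tsv = "84caf052da297d170e97ecb23a2abc6c"
)

#' Bundled plain-text fixtures, integrity-checked
#'
#' Returns the machine-readable copies of the published validation cohorts,
#' age-specific exposure parameters and provincial biomonitoring
#' concentrations, after verifying the packaged files against their
#' recorded checksums.
#'
#' @param dir Directory holding the fixture files; defaults to the
#'   installed package's `extdata`.
#' @return Named list of data frames: `validation_studies`,
#'   `exposure_parameters`, `biomonitoring`.
#' @export
bundled_fixtures <- function(dir = system.file("extdata", package = "fluopbpk")) {
  paths <- file.path(dir, names(.fixture_md5))
  found <- file.exists(paths)
  if (!all(found)) {
    abort_config(sprintf("missing fixture file(s): %s",
                         paste(names(.fixture_md5)[!found], collapse = ", ")))
  }
  sums <- tools::md5sum(paths)
  bad <- unname(sums) != unname(.fixture_md5)
  if (any(bad)) {
    abort_config(sprintf("fixture checksum mismatch: %s",
                         paste(names(.fixture_md5)[bad], collapse = ", ")))
  }
  list(
    validation_studies = read_validation_studies(paths[1]),
    exposure_parameters = utils::read.delim(paths[2]),
    biomonitoring = read_biomonitoring(paths[3])
  )
}
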