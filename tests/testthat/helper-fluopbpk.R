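# shared helpers for the suite

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# minimal synthetic simulation object for functions that only consume series
fake_sim <- function(per_day = NULL, time_min = NULL, venous = NULL,
                     duration_days = length(per_day)) {
  structure(
    list(per_day_excretion = per_day, time_min = time_min, venous = venous,
         duration_days = duration_days),
    class = "fluoride_sim"
  )
}

# a config with the sink-mode bone handling, otherwise default
sink_config <- function() {
  cfg <- default_config()
  cfg$bone_mode <- "sink"
  cfg
}

# calibrated 4-year-old bundle, shared across tests (session-memoised sims)
cal_bundle <- local({
  memo <- new.env(parent = emptyenv())
  function(age = 4) {
    key <- as.character(age)
    if (is.null(memo[[key]])) memo[[key]] <- calibrated_bundle(age)
    memo[[key]]
  }
})
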