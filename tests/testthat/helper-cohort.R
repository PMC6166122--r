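# shared synthetic fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

# full-size synthetic cohort at generator defaults (the study conditions):
# 150 participants x 2 sessions, ~780 pressed sequences
study_cohort <- function() {
  if (is.null(.fixtures$sessions))
    .fixtures$sessions <- simulate_cohort(n_participants = 150,
                                          n_sessions = 2, base_seed = 1)
  .fixtures$sessions
}

study_analysis <- function() {
  if (is.null(.fixtures$analysis))
    .fixtures$analysis <- analyze_cohort(study_cohort()[1:80])
  .fixtures$analysis
}

study_phase <- function() {
  if (is.null(.fixtures$phase)) {
    phase <- list()
    for (s in study_cohort()) {
      rec <- resample_to_master(s)
      res <- analyze_recording(rec)
      if (nrow(res$phase)) phase[[length(phase) + 1L]] <- res$phase
    }
    .fixtures$phase <- do.call(rbind, phase)
  }
  .fixtures$phase
}

# effect-free cohort (negative control)
null_analysis <- function() {
  if (is.null(.fixtures$null_analysis))
    .fixtures$null_analysis <- analyze_cohort(
      simulate_cohort(n_participants = 8, n_sessions = 2,
                      response = response_config_null(), base_seed = 2))
  .fixtures$null_analysis
}

# one short single-approach session for cheap unit tests
small_session <- function(seed = 11L) {
  simulate_session(scenario_config(trip_duration = 60,
                                   approaches_per_trip = 1),
                   response_config(seed = seed, press_probability = 1))
}
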