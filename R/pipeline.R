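#' Add derived analysis columns to a recording
#'
#' Computes the whole-trip preprocessing that the per-sequence analyses
#' share: smoothed binocular pupil diameter (`pupil`), whole-trip
#' luminance z-scores (`lum_z`), skin conductance in microsiemens with
#' movement-artifact samples removed (`scl_us`), using the band
#' accelerometer/gyroscope mask.
#'
#' @param rec a `"dsr_recording"`.
#' @param mask_args named list of overrides for [movement_mask()].
#' @return The recording with derived columns appended.
#' @export
augment_recording <- function(rec, mask_args = list()) {
  stopifnot(inherits(rec, "dsr_recording"))
  if (all(c("eye_pupil_left", "eye_pupil_right") %in% names(rec)))
    rec$pupil <- pupil_preprocess(rec$eye_pupil_left, rec$eye_pupil_right)
  if ("eye_luminance" %in% names(rec))
    rec$lum_z <- as.numeric(zscore(rec$eye_luminance, scope = "trip"))
  if (all(c("band_scl", "band_accel", "band_gyro") %in% names(rec))) {
    scl <- scl_convert(rec$band_scl)
    mask <- do.call(movement_mask,
                    c(list(accel = rec$band_accel, gyro = rec$band_gyro,
                           timestamps = rec$timestamp_s), mask_args))
    scl[mask] <- NA_real_
    rec$scl_us <- scl
  }
  rec
}

seq_zscore <- function(x) tryCatch(as.numeric(zscore(x)),
                                   error = function(e) NULL)

# per-sequence standardized percent profiles for every analysed parameter
sequence_profiles <- function(seqd) {
  d <- seqd$data
  out <- list()
  if (all(c("pupil", "lum_z") %in% names(d))) {
    pz <- seq_zscore(d$pupil)
    if (!is.null(pz))
      out$pupil_adj <- percent_resample(seqd, "pupil_adj",
                                        luminance_adjust(pz, d$lum_z))
  }
  if ("blinks_timer" %in% names(d)) {
    tz <- seq_zscore(d$blinks_timer)
    if (!is.null(tz))
      out$interblink <- percent_resample(seqd, "interblink", tz)
  }
  if ("band_hr" %in% names(d)) {
    hz <- seq_zscore(d$band_hr)
    if (!is.null(hz)) out$hr <- percent_resample(seqd, "hr", hz)
  }
  if ("scl_us" %in% names(d)) {
    sz <- seq_zscore(d$scl_us)
    if (!is.null(sz) && sum(!is.na(sz)) >= 3) {
      det <- detrend_linear(sz, d$timestamp_s)
      out$scl_detrended <- percent_resample(seqd, "scl_detrended", det)
    }
  }
  if ("mocap_shoulder_z" %in% names(d)) {
    disp <- displacement_from_start(d$mocap_shoulder_z)
    dz <- seq_zscore(as.numeric(disp))
    if (!is.null(dz)) out$shoulder_z <- percent_resample(seqd, "shoulder_z", dz)
  }
  if ("pressure_back" %in% names(d)) {
    prz <- seq_zscore(d$pressure_back)
    if (!is.null(prz))
      out$pressure_back <- percent_resample(seqd, "pressure_back", prz)
  }
  out
}

# per-sequence scalar metrics: blink rate and RMSSD for the three phases
sequence_phase_metrics <- function(seqd, blink_onsets) {
  d <- seqd$data
  on <- seqd$interval$onset; off <- seqd$interval$offset
  t0 <- d$timestamp_s[1]; t_end <- d$timestamp_s[nrow(d)]
  win <- list(pre = c(max(on - seqd$window, t0), on),
              during = c(on, off),
              post = c(off, min(off + seqd$window, t_end)))
  rows <- list()
  if (!is.null(blink_onsets)) {
    v <- vapply(win, function(wn) blink_rate(blink_onsets, wn[1], wn[2]), 0)
    rows$blink <- data.frame(metric = "blink_rate", pre = v[["pre"]],
                             during = v[["during"]], post = v[["post"]])
  }
  if ("band_ibi" %in% names(d)) {
    v <- vapply(win, function(wn) {
      ib <- d$band_ibi[d$timestamp_s >= wn[1] & d$timestamp_s < wn[2]]
      as.numeric(rmssd(ib))
    }, 0)
    rows$rmssd <- data.frame(metric = "rmssd", pre = v[["pre"]],
                             during = v[["during"]], post = v[["post"]])
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Analyse one recording end to end
#'
#' Extracts discomfort intervals from the handset channel, builds the
#' event-locked sequences, applies every per-parameter transform
#' (luminance-adjusted pupil z, interblink-timer z, HR z, masked and
#' detrended SCL z, shoulder-z displacement z, back-pressure z), percent-
#' resamples each onto the 0-300% scale and computes the per-interval
#' blink-rate and RMSSD phase metrics.
#'
#' @param rec a `"dsr_recording"` (it is [augment_recording()]-ed
#'   internally if needed).
#' @param ... passed to [extract_intervals()].
#' @return `list(intervals, profiles, phase)` where `profiles` is a
#'   named list (per channel) of `"dsr_profile"` lists and `phase` a
#'   data frame `sequence_id, metric, pre, during, post`.
#' @export
analyze_recording <- function(rec, ...) {
  if (!"scl_us" %in% names(rec)) rec <- augment_recording(rec)
  intervals <- extract_intervals(rec, ...)
  blinks <- attr(rec, "events")$blinks
  onsets <- if (!is.null(blinks)) blinks$data$onset_s else NULL
  pid <- attr(rec, "participant"); sid <- attr(rec, "session")

  profiles <- list()
  phase <- list()
  for (i in seq_len(nrow(intervals))) {
    seqd <- build_sequence(rec, intervals[i, ], all_intervals = intervals)
    prof <- sequence_profiles(seqd)
    for (nm in names(prof))
      profiles[[nm]] <- c(profiles[[nm]], list(prof[[nm]]))
    pm <- sequence_phase_metrics(seqd, onsets)
    if (!is.null(pm)) {
      pm$sequence_id <- paste(pid, sid, i, sep = "_")
      phase[[length(phase) + 1L]] <- pm
    }
  }
  phase <- if (length(phase)) {
    ph <- do.call(rbind, phase)
    rownames(ph) <- NULL
    ph[, c("sequence_id", "metric", "pre", "during", "post")]
  } else data.frame(sequence_id = character(0), metric = character(0),
                    pre = numeric(0), during = numeric(0),
                    post = numeric(0))
  list(intervals = intervals, profiles = profiles, phase = phase)
}

#' Analyse a set of sessions and aggregate across sequences
#'
#' Runs [analyze_recording()] over every session, pools the per-sequence
#' percent profiles per channel, and aggregates them into mean curves
#' with pointwise 95% CI bands plus the phase-metric summary table.
#'
#' @param sessions list of `"dsr_session"` objects (or of
#'   `"dsr_recording"`s).
#' @param ... passed to [extract_intervals()].
#' @return `list(aggregates, phase_table, phase, intervals, stats,
#'   profiles)`; `aggregates` is a named list of `"dsr_aggregate"`
#'   tables, `stats` the interval count/duration bookkeeping.
#' @export
analyze_cohort <- function(sessions, ...) {
  profiles <- list()
  phase <- list()
  ints <- list()
  for (s in sessions) {
    rec <- if (inherits(s, "dsr_recording")) s else resample_to_master(s)
    res <- analyze_recording(rec, ...)
    for (nm in names(res$profiles))
      profiles[[nm]] <- c(profiles[[nm]], res$profiles[[nm]])
    if (nrow(res$phase)) phase[[length(phase) + 1L]] <- res$phase
    if (nrow(res$intervals)) ints[[length(ints) + 1L]] <- res$intervals
  }
  phase <- if (length(phase)) do.call(rbind, phase) else
    data.frame(sequence_id = character(0), metric = character(0),
               pre = numeric(0), during = numeric(0), post = numeric(0))
  intervals <- if (length(ints)) do.call(rbind, ints) else
    data.frame(onset = numeric(0), offset = numeric(0),
               duration = numeric(0), peak = numeric(0))
  aggregates <- lapply(profiles, function(pl)
    if (length(pl) >= 2) aggregate_profiles(pl) else NULL)
  aggregates <- aggregates[!vapply(aggregates, is.null, TRUE)]
  list(aggregates = aggregates,
       phase_table = if (nrow(phase) >= 2) phase_table(phase) else NULL,
       phase = phase, intervals = intervals,
       stats = interval_stats(intervals), profiles = profiles)
}

#' Detect and evaluate over a set of sessions
#'
#' Runs the online detector on every session and scores it against the
#' handset-extracted intervals of the same session.
#'
#' @param sessions list of `"dsr_session"` or `"dsr_recording"` objects.
#' @param cfg a [detector_config()].
#' @param min_overlap passed to [evaluate_detection()].
#' @param ... passed to [extract_intervals()].
#' @return Data frame with one row per session: hit rate, false alarms,
#'   false-alarm rate per minute, median latency, counts.
#' @export
detect_cohort <- function(sessions, cfg = detector_config(),
                          min_overlap = 0, ...) {
  rows <- lapply(sessions, function(s) {
    rec <- if (inherits(s, "dsr_recording")) s else resample_to_master(s)
    truth <- extract_intervals(rec, ...)
    det <- detect(rec, cfg)
    ev <- evaluate_detection(det, truth, min_overlap)
    data.frame(hit_rate = ev$hit_rate, false_alarms = ev$false_alarms,
               false_alarm_rate_per_min = ev$false_alarm_rate_per_min,
               median_latency = ev$median_latency, n_truth = ev$n_truth,
               n_detected = ev$n_detected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
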