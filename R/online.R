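#' Online detector configuration
#'
#' Per-channel sliding baseline windows, directional thresholds in SD
#' units, fusion weights, score threshold and refractory period for the
#' prototype real-time discomfort detector. The default monitors heart
#' rate (threshold -0.3 SD, the operating point suggested by the
#' offline event-locked HR profile),
#' smoothed pupil diameter, shoulder z-position and back-sensor seat
#' pressure — the parameters with the strongest episode-locked changes.
#' Skin conductance is deliberately not monitored, and the interblink
#' timer is left out of the default vote as too unstable over short
#' episodes (both can be added through `channels`). Each channel is
#' standardized against two causal baseline windows (10 s ending 3 s
#' before now, 5 s ending 5 s before now) and contributes binary
#' evidence when either sliding z crosses its threshold.
#'
#' @param channels named list; each element is a list with `threshold`
#'   (signed SD units; sign gives direction) and optional `windows`, a
#'   list of `c(length, onset)` pairs in seconds.
#' @param weights named fusion weights, `>= 0`, summing to 1 (default
#'   equal).
#' @param score_threshold weighted-vote level that opens an episode
#'   (default 0.95: all four equally weighted default channels must
#'   agree, which keeps false alarms below one per trip while the
#'   sustained multi-channel episode effects are still caught).
#' @param refractory minimum separation between episodes in seconds;
#'   closer detections are merged (default 5).
#' @param windows default baseline windows used by channels that do not
#'   override them.
#' @return A list of class `"dsr_detector_config"`.
#' @export
detector_config <- function(channels = NULL, weights = NULL,
                            score_threshold = 0.95, refractory = 5,
                            windows = list(c(10, 3), c(5, 5))) {
  if (is.null(channels))
    channels <- list(
      band_hr = list(threshold = -0.3),
      pupil = list(threshold = 2),
      mocap_shoulder_z = list(threshold = -2),
      pressure_back = list(threshold = 2))
  for (nm in names(channels))
    if (is.null(channels[[nm]]$windows)) channels[[nm]]$windows <- windows
  if (is.null(weights))
    weights <- stats::setNames(rep(1 / length(channels), length(channels)),
                               names(channels))
  weights <- weights[names(channels)]
  if (any(is.na(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("fusion weights must be >= 0 for every monitored channel and sum to 1")
  for (ch in channels)
    for (w in ch$windows)
      if (w[1] <= 0 || w[2] < 0)
        stop("baseline windows need length > 0 and onset >= 0")
  structure(list(channels = channels, weights = weights,
                 score_threshold = score_threshold,
                 refractory = refractory),
            class = "dsr_detector_config")
}

#' Causal sliding-window z-standardization
#'
#' At each tick `t` the current sample is standardized against the mean
#' and SD of the samples in the baseline window
#' `[t - onset - length, t - onset]`, which lies entirely in the past:
#' the output at `t` never depends on samples after `t`. Windows with
#' fewer than `min_samples` values give a missing output; a zero-SD
#' window gives 0 (degenerate rule, mirroring [zscore()]).
#'
#' @param x series on the master timeline.
#' @param timestamps tick times (s).
#' @param length window length in seconds.
#' @param onset window end, seconds before now.
#' @param min_samples minimum non-missing samples in the window
#'   (default 5).
#' @return Series of SD units, `NA` where the window is unusable.
#' @export
sliding_z <- function(x, timestamps, length = 10, onset = 3,
                      min_samples = 5L) {
  n <- base::length(x)
  v <- ifelse(is.na(x), 0, x)
  k <- as.numeric(!is.na(x))
  cs_v <- c(0, cumsum(v))
  cs_v2 <- c(0, cumsum(v^2))
  cs_k <- c(0, cumsum(k))
  # window [t - onset - length, t - onset]: indices (lo-1, hi] via cumsums
  lo <- findInterval(timestamps - onset - length, timestamps,
                     left.open = TRUE)          # last tick < window start
  hi <- findInterval(timestamps - onset, timestamps)  # last tick <= window end
  cnt <- cs_k[hi + 1L] - cs_k[lo + 1L]
  sm <- cs_v[hi + 1L] - cs_v[lo + 1L]
  sq <- cs_v2[hi + 1L] - cs_v2[lo + 1L]
  ok <- cnt >= min_samples & hi >= 1L
  mu <- ifelse(ok, sm / pmax(cnt, 1), NA_real_)
  varw <- ifelse(ok, pmax(sq / pmax(cnt, 1) - mu^2, 0) *
                   cnt / pmax(cnt - 1, 1), NA_real_)
  sdw <- sqrt(varw)
  z <- rep(NA_real_, n)
  usable <- ok & !is.na(x)
  zero_sd <- usable & sdw < 1e-12
  z[usable] <- (x[usable] - mu[usable]) / sdw[usable]
  z[zero_sd] <- 0
  z
}

# derived monitored channels computed from a recording
prepare_monitored <- function(rec) {
  out <- list()
  if (all(c("eye_pupil_left", "eye_pupil_right") %in% names(rec)))
    out$pupil <- pupil_preprocess(rec$eye_pupil_left, rec$eye_pupil_right)
  for (nm in names(rec))
    if (nm != "timestamp_s") out[[nm]] <- rec[[nm]]
  out
}

#' Run the online discomfort detector over a recording
#'
#' For every monitored channel, binary evidence fires at tick `t` when
#' the causal sliding z crosses the channel's directional threshold in
#' any of its configured baseline windows. The discomfort score is the
#' weighted sum of the evidence; episodes are maximal runs with score at
#' or above the score threshold, merged when separated by less than the
#' refractory period.
#'
#' @param rec a `"dsr_recording"`.
#' @param cfg a [detector_config()].
#' @return A list of class `"dsr_detection"`: `score` series,
#'   `episodes` data frame (`onset, offset, peak_score, channels`), and
#'   the per-channel evidence matrix.
#' @export
detect <- function(rec, cfg = detector_config()) {
  stopifnot(inherits(rec, "dsr_recording"),
            inherits(cfg, "dsr_detector_config"))
  monitored <- prepare_monitored(rec)
  missing_ch <- setdiff(names(cfg$channels), names(monitored))
  if (length(missing_ch))
    stop("monitored channel(s) not present in recording: ",
         paste(missing_ch, collapse = ", "))
  ts <- rec$timestamp_s
  n <- length(ts)
  evidence <- matrix(0, n, length(cfg$channels),
                     dimnames = list(NULL, names(cfg$channels)))
  for (nm in names(cfg$channels)) {
    spec <- cfg$channels[[nm]]
    hit <- rep(FALSE, n)
    for (w in spec$windows) {
      z <- sliding_z(monitored[[nm]], ts, w[1], w[2])
      hit <- hit | (!is.na(z) &
                      if (spec$threshold < 0) z <= spec$threshold
                      else z >= spec$threshold)
    }
    evidence[, nm] <- as.numeric(hit)
  }
  score <- as.numeric(evidence %*% cfg$weights[names(cfg$channels)])

  above <- score >= cfg$score_threshold
  eps <- data.frame(onset = numeric(0), offset = numeric(0),
                    peak_score = numeric(0), channels = character(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    merged <- runs[1, ]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        j <- nrow(merged)
        if (ts[runs$start[i]] - ts[merged$end[j]] < cfg$refractory) {
          merged$end[j] <- runs$end[i]
        } else merged <- rbind(merged, runs[i, ])
      }
    }
    eps <- data.frame(
      onset = ts[merged$start], offset = ts[merged$end],
      peak_score = vapply(seq_len(nrow(merged)), function(i)
        max(score[merged$start[i]:merged$end[i]]), 0),
      channels = vapply(seq_len(nrow(merged)), function(i) {
        seg <- merged$start[i]:merged$end[i]
        paste(colnames(evidence)[colSums(evidence[seg, , drop = FALSE]) > 0],
              collapse = "+")
      }, ""))
  }
  structure(list(timestamp_s = ts, score = score, episodes = eps,
                 evidence = evidence, config = cfg),
            class = "dsr_detection")
}

#' Evaluate detections against ground-truth intervals
#'
#' A truth interval is hit when a detected episode overlaps at least
#' `min_overlap` of it; unmatched detections are false alarms. Latency
#' is detection onset minus truth onset for hit intervals (an episode
#' already open when the truth interval starts has negative latency).
#'
#' @param detection a `"dsr_detection"` (or a data frame with
#'   `onset`/`offset`).
#' @param truth a `"dsr_intervals"` table.
#' @param min_overlap minimum overlapped fraction of the truth interval
#'   (default 0, i.e. any overlap).
#' @return `list(hit_rate, false_alarms, false_alarm_rate_per_min,
#'   median_latency, n_truth, n_detected)`.
#' @export
evaluate_detection <- function(detection, truth, min_overlap = 0) {
  eps <- if (inherits(detection, "dsr_detection")) detection$episodes
  else detection
  span <- if (inherits(detection, "dsr_detection"))
    diff(range(detection$timestamp_s)) else NA_real_

  n_truth <- nrow(truth)
  hit <- logical(n_truth)
  latency <- rep(NA_real_, n_truth)
  used <- logical(nrow(eps))
  for (i in seq_len(n_truth)) {
    if (!nrow(eps)) break
    ov <- pmin(eps$offset, truth$offset[i]) - pmax(eps$onset, truth$onset[i])
    need <- min_overlap * (truth$offset[i] - truth$onset[i])
    cand <- which(ov > 0 & ov >= need)
    if (length(cand)) {
      hit[i] <- TRUE
      first <- cand[which.min(eps$onset[cand])]
      latency[i] <- eps$onset[first] - truth$onset[i]
      used[cand] <- TRUE
    }
  }
  fa <- sum(!used)
  list(hit_rate = if (n_truth) mean(hit) else NA_real_,
       false_alarms = fa,
       false_alarm_rate_per_min = if (is.na(span) || span <= 0) NA_real_
       else fa / (span / 60),
       median_latency = if (any(hit)) stats::median(latency[hit])
       else NA_real_,
       n_truth = n_truth, n_detected = nrow(eps))
}
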