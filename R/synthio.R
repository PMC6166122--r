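#' Scenario configuration for the simulated close-approach trip
#'
#' Defines the longitudinal kinematics of one automated trip: the ego
#' vehicle closes in on a slower lead truck, automated braking starts very
#' late at `brake_onset_gap` and nulls the relative speed exactly at
#' `min_gap`; after a short dwell the ego car falls back to `reset_gap`
#' and the next approach begins.
#'
#' @param ego_speed ego vehicle speed in km/h (default 100).
#' @param lead_speed lead truck speed in km/h (default 80).
#' @param brake_onset_gap bumper-to-bumper gap at brake onset, m (default 9).
#' @param min_gap minimum gap reached, m (default 4.2).
#' @param reset_gap gap restored between approaches, m (default 100).
#' @param approaches_per_trip number of approach manoeuvres (default 3).
#' @param trip_duration trip length in seconds (default 180).
#' @param master_rate master timeline rate in Hz (default 60).
#' @param dwell seconds spent at `min_gap` before falling back (default 2).
#' @return A list of class `"dsr_scenario"`.
#' @export
scenario_config <- function(ego_speed = 100, lead_speed = 80,
                            brake_onset_gap = 9, min_gap = 4.2,
                            reset_gap = 100, approaches_per_trip = 3,
                            trip_duration = 180, master_rate = 60,
                            dwell = 2) {
  cfg <- list(ego_speed = ego_speed, lead_speed = lead_speed,
              brake_onset_gap = brake_onset_gap, min_gap = min_gap,
              reset_gap = reset_gap,
              approaches_per_trip = as.integer(approaches_per_trip),
              trip_duration = trip_duration, master_rate = master_rate,
              dwell = dwell)
  if (ego_speed < lead_speed)
    stop("infeasible scenario: ego_speed must not be below lead_speed")
  if (!(0 < min_gap && min_gap < brake_onset_gap &&
        brake_onset_gap < reset_gap))
    stop("infeasible scenario: need 0 < min_gap < brake_onset_gap < reset_gap")
  if (master_rate <= 0 || trip_duration <= 0 || approaches_per_trip < 1 ||
      dwell < 0)
    stop("infeasible scenario: rates, durations and counts must be positive")
  structure(cfg, class = "dsr_scenario")
}

#' Response configuration for the synthetic participant
#'
#' Collects every tunable of the synthetic handset and physiology
#' generator: press behaviour, phase-dependent blink rates, pupil dilation
#' and luminance coupling, heart-rate deceleration with mid-episode
#' plateau, RMSSD suppression, skin-conductance drift and movement
#' artifacts, and the push-back body response. Defaults encode the study
#' conditions: presses in about 208/240 approaches with log-normal
#' durations of mean 8.10 s / SD 5.52 s, blink rates 0.25/0.17/0.37 per s
#' before/during/after an episode, and a heart-rate plateau from the
#' episode midpoint until about 5 s after release.
#'
#' @param press_probability probability a given approach elicits a press.
#' @param press_duration_mean,press_duration_sd mean and SD (s) of the
#'   log-normal press-duration law (truncated at 0.5 s).
#' @param press_onset_lag mean lag (s) from brake onset to press onset.
#' @param press_onset_jitter_sd SD (s) of the onset lag jitter.
#' @param blink_rate_pre,blink_rate_during,blink_rate_post blink rates
#'   (events per s) outside episodes, inside episodes, and in the 10 s
#'   after release.
#' @param pupil_baseline baseline pupil diameter, mm.
#' @param pupil_dilation_amplitude peak episode dilation, mm.
#' @param luminance_coupling_gain pupil change per unit scene luminance,
#'   mm (the looming white truck raises luminance as the gap closes).
#' @param hr_baseline baseline heart rate, bpm.
#' @param hr_deceleration_amplitude depth of the episode HR deceleration,
#'   bpm.
#' @param hr_recovery_delay seconds after release before HR recovery
#'   starts.
#' @param rmssd_baseline baseline RMSSD of the interbeat intervals, s.
#' @param rmssd_suppression_factor multiplier in `[0, 1]` applied to
#'   beat-to-beat variability inside episodes.
#' @param scl_baseline baseline skin conductance, microsiemens.
#' @param scl_drift_rate linear conductance drift, microsiemens per s.
#' @param artifact_rate movement-artifact rate, events per minute.
#' @param pushback_amplitude peak rearward shoulder displacement, mm
#'   (drop in the z-position).
#' @param pressure_amplitude peak back-sensor seat-pressure increase,
#'   sensor units.
#' @param noise_sd named list of per-channel noise SDs; partial lists are
#'   merged over the defaults.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return A list of class `"dsr_response"`.
#' @export
response_config <- function(press_probability = 208 / 240,
                            press_duration_mean = 8.10,
                            press_duration_sd = 5.52,
                            press_onset_lag = 0.5,
                            press_onset_jitter_sd = 0.2,
                            blink_rate_pre = 0.25,
                            blink_rate_during = 0.17,
                            blink_rate_post = 0.37,
                            pupil_baseline = 3.5,
                            pupil_dilation_amplitude = 0.3,
                            luminance_coupling_gain = 0.6,
                            hr_baseline = 72,
                            hr_deceleration_amplitude = 4,
                            hr_recovery_delay = 5,
                            rmssd_baseline = 0.035,
                            rmssd_suppression_factor = 0.6,
                            scl_baseline = 4,
                            scl_drift_rate = 0.01,
                            artifact_rate = 2,
                            pushback_amplitude = 15,
                            pressure_amplitude = 40,
                            noise_sd = list(),
                            seed = 1L) {
  default_noise <- list(pupil = 0.05, luminance = 0.05, hr = 1.2,
                        scl = 0.05, accel = 0.02, gyro = 3,
                        shoulder = 2, pressure = 8)
  noise <- utils::modifyList(default_noise, as.list(noise_sd))
  cfg <- list(press_probability = press_probability,
              press_duration_mean = press_duration_mean,
              press_duration_sd = press_duration_sd,
              press_onset_lag = press_onset_lag,
              press_onset_jitter_sd = press_onset_jitter_sd,
              blink_rate_pre = blink_rate_pre,
              blink_rate_during = blink_rate_during,
              blink_rate_post = blink_rate_post,
              pupil_baseline = pupil_baseline,
              pupil_dilation_amplitude = pupil_dilation_amplitude,
              luminance_coupling_gain = luminance_coupling_gain,
              hr_baseline = hr_baseline,
              hr_deceleration_amplitude = hr_deceleration_amplitude,
              hr_recovery_delay = hr_recovery_delay,
              rmssd_baseline = rmssd_baseline,
              rmssd_suppression_factor = rmssd_suppression_factor,
              scl_baseline = scl_baseline,
              scl_drift_rate = scl_drift_rate,
              artifact_rate = artifact_rate,
              pushback_amplitude = pushback_amplitude,
              pressure_amplitude = pressure_amplitude,
              noise_sd = noise, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), c("noise_sd", "seed"))])
  if (any(!is.finite(num))) stop("response config: all values must be finite")
  if (press_probability < 0 || press_probability > 1)
    stop("press_probability must be in [0, 1]")
  if (rmssd_suppression_factor < 0 || rmssd_suppression_factor > 1)
    stop("rmssd_suppression_factor must be in [0, 1]")
  structure(cfg, class = "dsr_response")
}

#' Null-effect response configuration
#'
#' Returns a [response_config()] whose discomfort-locked effects are all
#' zero: equal blink rates across phases, no episode dilation, no HR
#' deceleration, no RMSSD suppression, no push-back. The pupillary light
#' reflex (`luminance_coupling_gain`) is deliberately kept at its
#' default: it is nuisance physiology present whether or not the
#' participant is uncomfortable, and the false-positive control must
#' exercise the luminance correction under exactly that condition.
#'
#' @param ... overrides passed on to [response_config()].
#' @return A `"dsr_response"` configuration.
#' @export
response_config_null <- function(...) {
  response_config(blink_rate_during = 0.25, blink_rate_post = 0.25,
                  pupil_dilation_amplitude = 0,
                  hr_deceleration_amplitude = 0,
                  rmssd_suppression_factor = 1,
                  pushback_amplitude = 0, pressure_amplitude = 0, ...)
}

#' Simulate the longitudinal kinematics of one trip
#'
#' Deterministic piecewise trajectory of the gap between ego car and lead
#' truck. Each approach closes at constant relative speed, brakes with the
#' constant deceleration that nulls the relative speed exactly at
#' `min_gap`, dwells, then falls back to `reset_gap` at the original
#' closing speed. Time to contact (TTC) is defined only while closing.
#'
#' @param config a [scenario_config()].
#' @return A data frame of class `"dsr_kinematics"` with columns
#'   `time`, `gap` (m), `ego_speed` and `lead_speed` (m/s) and `ttc` (s,
#'   `NA` when not closing), one row per master tick, plus an
#'   `"approaches"` attribute with the per-approach phase times.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "dsr_scenario"))
  v_lead <- config$lead_speed / 3.6
  v0 <- (config$ego_speed - config$lead_speed) / 3.6   # closing speed m/s
  n <- as.integer(round(config$trip_duration * config$master_rate))
  t <- (seq_len(n) - 1L) / config$master_rate
  if (v0 == 0) {               # zero closing speed: constant gap, no approach
    out <- data.frame(time = t, gap = rep(config$reset_gap, n),
                      ego_speed = v_lead, lead_speed = v_lead,
                      ttc = NA_real_)
    attr(out, "approaches") <- data.frame(
      approach = integer(0), t_start = numeric(0),
      t_brake_onset = numeric(0), t_min_gap = numeric(0),
      t_reset = numeric(0))
    attr(out, "config") <- config
    class(out) <- c("dsr_kinematics", "data.frame")
    return(out)
  }
  decel <- v0^2 / (2 * (config$brake_onset_gap - config$min_gap))
  t_close <- (config$reset_gap - config$brake_onset_gap) / v0
  t_brake <- v0 / decel
  t_fall  <- (config$reset_gap - config$min_gap) / v0
  cycle <- t_close + t_brake + config$dwell + t_fall

  gap <- rep(config$reset_gap, n)
  vrel <- rep(0, n)

  sched <- data.frame(approach = seq_len(config$approaches_per_trip))
  sched$t_start <- (sched$approach - 1L) * cycle
  sched$t_brake_onset <- sched$t_start + t_close
  sched$t_min_gap <- sched$t_brake_onset + t_brake
  sched$t_reset <- sched$t_min_gap + config$dwell + t_fall
  if (sched$t_reset[nrow(sched)] > config$trip_duration)
    warning("trip_duration too short: ",
            sum(sched$t_brake_onset > config$trip_duration),
            " scheduled approaches truncated")

  for (k in seq_len(nrow(sched))) {
    s <- sched[k, ]
    ph <- t >= s$t_start & t < s$t_brake_onset          # closing
    tau <- t[ph] - s$t_start
    gap[ph] <- config$reset_gap - v0 * tau
    vrel[ph] <- v0
    ph <- t >= s$t_brake_onset & t < s$t_min_gap        # braking
    tau <- t[ph] - s$t_brake_onset
    gap[ph] <- config$brake_onset_gap - v0 * tau + 0.5 * decel * tau^2
    vrel[ph] <- v0 - decel * tau
    ph <- t >= s$t_min_gap & t < s$t_min_gap + config$dwell   # dwell
    gap[ph] <- config$min_gap
    vrel[ph] <- 0
    ph <- t >= s$t_min_gap + config$dwell & t < s$t_reset     # fall back
    tau <- t[ph] - (s$t_min_gap + config$dwell)
    gap[ph] <- config$min_gap + v0 * tau
    vrel[ph] <- -v0
  }

  ttc <- ifelse(vrel > 0, gap / vrel, NA_real_)
  out <- data.frame(time = t, gap = gap,
                    ego_speed = v_lead + vrel, lead_speed = v_lead,
                    ttc = ttc)
  attr(out, "approaches") <- sched
  attr(out, "config") <- config
  class(out) <- c("dsr_kinematics", "data.frame")
  out
}

# truncated log-normal draws with the requested arithmetic mean/sd
rlnorm_mean_sd <- function(n, mean, sd, lower = 0.5) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  out <- stats::rlnorm(n, mu, sqrt(sigma2))
  while (any(bad <- out <= lower))
    out[bad] <- stats::rlnorm(sum(bad), mu, sqrt(sigma2))
  out
}

# half-cosine rise/hold/fall pulse of unit peak on times t
smooth_pulse <- function(t, onset, offset, ramp = 0.3) {
  ramp <- min(ramp, (offset - onset) / 2)
  y <- numeric(length(t))
  up <- t >= onset & t < onset + ramp
  y[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp))
  hold <- t >= onset + ramp & t <= offset - ramp
  y[hold] <- 1
  dn <- t > offset - ramp & t <= offset
  y[dn] <- 0.5 * (1 - cos(pi * (offset - t[dn]) / ramp))
  y
}

# symmetric inverse-u bump (0 at edges, 1 at midpoint)
sine_bump <- function(t, onset, offset) {
  y <- numeric(length(t))
  inside <- t >= onset & t <= offset
  y[inside] <- sin(pi * (t[inside] - onset) / (offset - onset))
  y
}

#' Simulate the handset discomfort report
#'
#' For each scheduled approach, with probability `press_probability`, one
#' press episode is emitted: onset near brake onset plus a jittered lag,
#' duration drawn from a truncated log-normal, magnitude a smooth ramp up
#' to a peak in `(0, 1]`. The channel is zero outside episodes.
#'
#' @param kin a [simulate_scenario()] trace.
#' @param rc a [response_config()]; draws come from the current RNG
#'   stream (seed management is done by [simulate_session()]).
#' @return A 60 Hz `"dsr_channel"` named `"handset"`, with the true
#'   episode table in the `"episodes"` attribute.
#' @export
simulate_handset <- function(kin, rc = response_config()) {
  stopifnot(inherits(kin, "dsr_kinematics"), inherits(rc, "dsr_response"))
  sched <- attr(kin, "approaches")
  cfg <- attr(kin, "config")
  t <- kin$time
  trip_end <- t[length(t)]
  value <- numeric(length(t))

  eps <- list()
  for (k in seq_len(nrow(sched))) {
    if (sched$t_brake_onset[k] >= trip_end) next
    if (stats::runif(1) > rc$press_probability) next
    lag <- rc$press_onset_lag +
      stats::rnorm(1, 0, rc$press_onset_jitter_sd)
    onset <- sched$t_brake_onset[k] + max(lag, 0.05)
    dur <- rlnorm_mean_sd(1, rc$press_duration_mean, rc$press_duration_sd)
    offset <- min(onset + dur, trip_end - 0.2)
    if (k < nrow(sched))          # keep episodes of adjacent approaches apart
      offset <- min(offset, sched$t_brake_onset[k + 1] - 1)
    if (offset - onset < 0.5) next
    peak <- stats::runif(1, 0.4, 1)
    value <- value + peak * smooth_pulse(t, onset, offset)
    eps[[length(eps) + 1L]] <- data.frame(
      approach = sched$approach[k], onset = onset, offset = offset,
      duration = offset - onset, peak = peak)
  }
  episodes <- if (length(eps)) do.call(rbind, eps) else
    data.frame(approach = integer(), onset = numeric(), offset = numeric(),
               duration = numeric(), peak = numeric())
  ch <- channel("handset", t, pmin(value, 1), cfg$master_rate, "fraction")
  attr(ch, "episodes") <- episodes
  ch
}

# moving-average-smoothed gaussian noise, sd preserved
smooth_noise <- function(n, sd, rate, tau = 0.5) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  w <- max(1L, as.integer(round(tau * rate)))
  x <- stats::rnorm(n + w - 1L)
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[w:(n + w - 1L)]
  y * sd * sqrt(w)
}

# inhomogeneous Poisson (exponential-gap renewal) blink onsets by
# thinning; no minimum-separation rejection, so the configured phase
# rates are realized without bias (onsets closer than one blink length
# are rare and harmless: their missing-data spans simply union)
draw_blinks <- function(trip_end, rate_fn, rmax) {
  onsets <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, rmax)
    if (t >= trip_end) break
    if (stats::runif(1) < rate_fn(t) / rmax)
      onsets <- c(onsets, t)
  }
  onsets
}

#' Simulate all physiological and body-motion channels
#'
#' Emits, at the native device rates, every sensor stream of the study
#' suite, with the configured episode-locked effect templates keyed to the
#' true handset episodes: pupil dilation plus luminance coupling, blink
#' thinning, HR deceleration with mid-episode plateau and delayed
#' recovery, beat-wise IBI with suppressed variability, drifting skin
#' conductance with movement artifacts mirrored in accelerometer and
#' gyroscope spikes, shoulder push-back, and back-sensor seat pressure.
#'
#' @param kin a [simulate_scenario()] trace.
#' @param handset the [simulate_handset()] channel (its `"episodes"`
#'   attribute drives the effect templates).
#' @param rc a [response_config()].
#' @return `list(channels = <named list of dsr_channel>,
#'   events = list(blinks = dsr_events))`.
#' @export
simulate_physiology <- function(kin, handset, rc = response_config()) {
  stopifnot(inherits(kin, "dsr_kinematics"))
  cfg <- attr(kin, "config")
  ep <- attr(handset, "episodes")
  t60 <- kin$time
  trip_end <- t60[length(t60)]
  ns <- rc$noise_sd
  blink_len <- 0.12

  in_phase <- function(t, lo, hi) {   # any episode-relative window hit
    hit <- rep(FALSE, length(t))
    for (i in seq_len(nrow(ep)))
      hit <- hit | (t >= lo[i] & t < hi[i])
    hit
  }

  ## scene luminance: a looming-truck component affine in 1/gap (the
  ## white truck fills more of the camera view as it closes in) riding
  ## on ambient scenery variation that is present throughout the trip
  ## (passing trees, sky, road texture). The ambient share keeps trip-
  ## scope and sequence-scope luminance variability commensurate, which
  ## is the regime in which the whole-trip z-subtraction used for pupil
  ## correction is well conditioned. The pupil couples to the true
  ## luminance; the logged channel adds camera measurement noise.
  inv <- 1 / kin$gap
  truck <- (inv - min(inv)) / max(diff(range(inv)), .Machine$double.eps)
  ambient <- smooth_noise(length(t60), 0.2, cfg$master_rate, tau = 8)
  lum_true <- pmin(pmax(0.4 + 0.2 * truck + ambient, 0), 1)
  lum <- pmin(pmax(lum_true + stats::rnorm(length(t60), 0, ns$luminance),
                   0), 1)

  ## blink onsets: thinned renewal at the three phase rates
  rates <- c(pre = rc$blink_rate_pre, during = rc$blink_rate_during,
             post = rc$blink_rate_post)
  rate_fn <- function(tt) {
    for (i in seq_len(nrow(ep)))       # during-phase outranks a previous
      if (tt >= ep$onset[i] && tt < ep$offset[i])    # episode's post tail
        return(rates[["during"]])
    for (i in seq_len(nrow(ep)))
      if (tt >= ep$offset[i] && tt < ep$offset[i] + 10)
        return(rates[["post"]])
    rates[["pre"]]
  }
  onsets <- draw_blinks(trip_end, rate_fn, max(rates, 1e-9))
  blinks <- event_stream("blinks", onsets, rep(blink_len, length(onsets)))

  ## pupil: baseline + inverse-u dilation + luminance coupling + noise
  dil <- numeric(length(t60))
  for (i in seq_len(nrow(ep)))
    dil <- dil + rc$pupil_dilation_amplitude *
      sine_bump(t60, ep$onset[i], ep$offset[i])
  core <- rc$pupil_baseline + dil + rc$luminance_coupling_gain * lum_true
  in_blink <- rep(FALSE, length(t60))
  for (b in onsets)
    in_blink <- in_blink | (t60 >= b & t60 <= b + blink_len)
  pupil_l <- core + smooth_noise(length(t60), ns$pupil, cfg$master_rate, 0.3)
  pupil_r <- core + smooth_noise(length(t60), ns$pupil, cfg$master_rate, 0.3)
  pupil_l[in_blink] <- NA
  pupil_r[in_blink] <- NA

  ## heart rate: deceleration ramp, plateau from mid-episode to
  ## recovery_delay after release, then 2 s recovery
  t10 <- seq(0, trip_end, by = 0.1)
  hr_tmpl <- function(tt) {
    y <- numeric(length(tt))
    for (i in seq_len(nrow(ep))) {
      on <- ep$onset[i]; off <- ep$offset[i]
      mid <- on + (off - on) / 2
      rec0 <- off + rc$hr_recovery_delay
      seg <- tt >= on & tt < mid
      y[seg] <- y[seg] - rc$hr_deceleration_amplitude * (tt[seg] - on) / (mid - on)
      seg <- tt >= mid & tt < rec0
      y[seg] <- y[seg] - rc$hr_deceleration_amplitude
      seg <- tt >= rec0 & tt < rec0 + 2
      y[seg] <- y[seg] - rc$hr_deceleration_amplitude * (1 - (tt[seg] - rec0) / 2)
    }
    y
  }
  hr10 <- rc$hr_baseline + hr_tmpl(t10) +
    smooth_noise(length(t10), ns$hr, 10, 2)

  ## beats: IBI from the noiseless HR path plus high-frequency variability
  hf_sd <- rc$rmssd_baseline / sqrt(2)
  beats <- numeric(0); ibis <- numeric(0)
  tb <- stats::runif(1, 0, 1)
  while (tb < trip_end) {
    s <- hf_sd * if (nrow(ep) && any(tb >= ep$onset & tb < ep$offset))
      rc$rmssd_suppression_factor else 1
    ibi <- 60 / (rc$hr_baseline + hr_tmpl(tb)) + stats::rnorm(1, 0, s)
    ibi <- max(ibi, 0.3)
    beats <- c(beats, tb); ibis <- c(ibis, ibi)
    tb <- tb + ibi
  }
  idx <- pmax(findInterval(t10, beats), 1L)   # device holds last beat value
  ibi10 <- ibis[idx]

  ## skin conductance (device logs resistance in kOhm) + artifacts
  cond <- rc$scl_baseline + rc$scl_drift_rate * t10 +
    smooth_noise(length(t10), ns$scl, 10, 2)
  accel <- 1 + stats::rnorm(length(t10), 0, ns$accel)
  gyro <- abs(stats::rnorm(length(t10), 0, ns$gyro))
  n_art <- stats::rpois(1, rc$artifact_rate * trip_end / 60)
  art <- data.frame(onset = numeric(0), offset = numeric(0))
  if (n_art > 0) {
    a_on <- sort(stats::runif(n_art, 0, trip_end - 2))
    a_dur <- stats::runif(n_art, 0.5, 2)
    art <- data.frame(onset = a_on, offset = a_on + a_dur)
    for (i in seq_len(n_art)) {
      seg <- t10 >= art$onset[i] & t10 < art$offset[i]
      cond[seg] <- cond[seg] + stats::runif(1, 1, 3)
      accel[seg] <- accel[seg] + stats::runif(1, 0.3, 0.8)
      gyro[seg] <- gyro[seg] + stats::runif(1, 80, 150)
    }
  }
  cond <- pmax(cond, 0.5)

  ## body motion: shoulder rigid body at 120 Hz, pushback drops z
  t120 <- seq(0, trip_end - 1 / 120, by = 1 / 120)
  push <- numeric(length(t120))
  for (i in seq_len(nrow(ep)))
    push <- push + sine_bump(t120, ep$onset[i], ep$offset[i])
  sway <- function() smooth_noise(length(t120), ns$shoulder, 120, 1.5)
  sh_x <- 320 + sway() - 0.3 * rc$pushback_amplitude * push
  sh_y <- 540 + sway() + 0.3 * rc$pushback_amplitude * push
  sh_z <- 1400 + sway() - rc$pushback_amplitude * push

  ## seat pressure mat: 8 sensors, back sensor carries the pushback
  push10 <- numeric(length(t10))
  for (i in seq_len(nrow(ep)))
    push10 <- push10 + sine_bump(t10, ep$onset[i], ep$offset[i])
  pressure <- list()
  pressure$pressure_back <- 480 + rc$pressure_amplitude * push10 +
    smooth_noise(length(t10), ns$pressure, 10, 1)
  bases <- c(520, 560, 430, 450, 390, 410, 300)
  for (j in seq_along(bases))
    pressure[[paste0("pressure_s", j + 1)]] <-
      bases[j] + smooth_noise(length(t10), ns$pressure, 10, 1)

  chans <- list(
    sim_gap = channel("sim_gap", t60, kin$gap, cfg$master_rate, "m"),
    sim_ego_speed = channel("sim_ego_speed", t60, kin$ego_speed,
                            cfg$master_rate, "m/s"),
    sim_lead_speed = channel("sim_lead_speed", t60, kin$lead_speed,
                             cfg$master_rate, "m/s"),
    sim_ttc = channel("sim_ttc", t60, kin$ttc, cfg$master_rate, "s"),
    eye_pupil_left = channel("eye_pupil_left", t60, pupil_l, 60, "mm"),
    eye_pupil_right = channel("eye_pupil_right", t60, pupil_r, 60, "mm"),
    eye_luminance = channel("eye_luminance", t60, lum, 60, "fraction"),
    band_hr = channel("band_hr", t10, hr10, 10, "bpm"),
    band_ibi = channel("band_ibi", t10, ibi10, 10, "s"),
    band_scl = channel("band_scl", t10, 1000 / cond, 10, "kOhm"),
    band_accel = channel("band_accel", t10, accel, 10, "g"),
    band_gyro = channel("band_gyro", t10, gyro, 10, "deg/s"),
    mocap_shoulder_x = channel("mocap_shoulder_x", t120, sh_x, 120, "mm"),
    mocap_shoulder_y = channel("mocap_shoulder_y", t120, sh_y, 120, "mm"),
    mocap_shoulder_z = channel("mocap_shoulder_z", t120, sh_z, 120, "mm"))
  for (nm in names(pressure))
    chans[[nm]] <- channel(nm, t10, pressure[[nm]], 10, "raw")
  attr(chans$band_scl, "artifacts") <- art

  list(channels = chans, events = list(blinks = blinks))
}

#' Simulate one complete synthetic session
#'
#' Runs [simulate_scenario()], [simulate_handset()] and
#' [simulate_physiology()] under the configured seed and assembles a
#' session object with its provenance manifest. Identical configuration
#' and seed give bit-identical sessions; the caller's RNG state is left
#' untouched.
#'
#' @param scenario a [scenario_config()].
#' @param response a [response_config()] (its `seed` drives all draws).
#' @param participant,session identifier strings recorded in the
#'   manifest.
#' @return A `"dsr_session"`: `list(manifest, channels, events)` with the
#'   handset channel (and its true-episode table) included under
#'   `channels$handset`.
#' @export
simulate_session <- function(scenario = scenario_config(),
                             response = response_config(),
                             participant = "p01", session = "s1") {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(response$seed)

  kin <- simulate_scenario(scenario)
  handset <- simulate_handset(kin, response)
  phys <- simulate_physiology(kin, handset, response)
  chans <- c(list(handset = handset), phys$channels)

  manifest <- list(
    participant = participant, session = session, seed = response$seed,
    master_rate = scenario$master_rate,
    trip_duration = scenario$trip_duration,
    scenario = unclass(scenario), response = unclass(response),
    channels = data.frame(
      name = vapply(chans, function(ch) ch$name, ""),
      rate = vapply(chans, function(ch) ch$rate, 0),
      unit = vapply(chans, function(ch) ch$unit, ""),
      kind = "channel", row.names = NULL),
    events = data.frame(name = names(phys$events), kind = "events"))
  structure(list(manifest = manifest, channels = chans,
                 events = phys$events),
            class = "dsr_session")
}

fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), "")
  out
}

#' Write a session to disk as channel CSV logs plus a manifest
#'
#' One `timestamp_s,value` CSV per channel, one `onset_s,duration_s` CSV
#' per event stream, and a YAML manifest recording ids, seed, rates,
#' units and the generator configuration. Numeric values are written with
#' 17 significant digits so a write/read round trip is exact.
#'
#' @param dir output directory (created if needed).
#' @param session a `"dsr_session"`; alternatively pass `channels`,
#'   `events` and `manifest` explicitly.
#' @param channels,events,manifest components used when `session` is
#'   `NULL`; an empty channel list writes a manifest-only session.
#' @return The directory path, invisibly.
#' @export
write_session <- function(dir, session = NULL, channels = list(),
                          events = list(), manifest = list()) {
  if (!is.null(session)) {
    stopifnot(inherits(session, "dsr_session"))
    channels <- session$channels
    events <- session$events
    manifest <- session$manifest
  }
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create session directory: ", dir)

  chan_tab <- data.frame(
    name = vapply(channels, function(ch) ch$name, ""),
    file = vapply(channels, function(ch) paste0(ch$name, ".csv"), ""),
    rate = vapply(channels, function(ch) ch$rate, 0),
    unit = vapply(channels, function(ch) ch$unit, ""), row.names = NULL)
  ev_tab <- data.frame(
    name = vapply(events, function(ev) ev$name, ""),
    file = vapply(events, function(ev) paste0(ev$name, ".csv"), ""),
    row.names = NULL)

  for (ch in channels) {
    path <- file.path(dir, paste0(ch$name, ".csv"))
    df <- data.frame(timestamp_s = fmt_num(ch$data$timestamp_s),
                     value = fmt_num(ch$data$value))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  for (ev in events) {
    path <- file.path(dir, paste0(ev$name, ".csv"))
    df <- data.frame(onset_s = fmt_num(ev$data$onset_s),
                     duration_s = fmt_num(ev$data$duration_s))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }

  man <- manifest
  man$channels <- if (nrow(chan_tab))
    lapply(seq_len(nrow(chan_tab)), function(i) as.list(chan_tab[i, ]))
  else list()
  man$events <- if (nrow(ev_tab))
    lapply(seq_len(nrow(ev_tab)), function(i) as.list(ev_tab[i, ]))
  else list()
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Schedule a full study cohort
#'
#' Expands participants x sessions x approaches-per-trip into the table
#' of scheduled approach events (the study design yields
#' 40 x 2 x 3 = 240).
#'
#' @param n_participants,n_sessions cohort dimensions (defaults 40 and 2).
#' @param scenario a [scenario_config()] supplying approaches per trip
#'   and their brake-onset times.
#' @return Data frame `participant, session, approach, t_brake_onset`.
#' @export
plan_cohort <- function(n_participants = 40, n_sessions = 2,
                        scenario = scenario_config()) {
  kin <- simulate_scenario(scenario)
  sched <- attr(kin, "approaches")
  grid <- expand.grid(approach = sched$approach,
                      session = sprintf("s%d", seq_len(n_sessions)),
                      participant = sprintf("p%02d", seq_len(n_participants)),
                      stringsAsFactors = FALSE)
  grid$t_brake_onset <- sched$t_brake_onset[match(grid$approach,
                                                  sched$approach)]
  grid[, c("participant", "session", "approach", "t_brake_onset")]
}

#' Simulate a cohort of sessions
#'
#' One synthetic trip per participant x session cell, each with a seed
#' derived deterministically from `base_seed`, optionally written to disk.
#'
#' @param n_participants,n_sessions cohort dimensions.
#' @param scenario a [scenario_config()].
#' @param response a [response_config()] template; its seed is replaced
#'   per trip.
#' @param base_seed integer seeding a master stream from which the
#'   per-trip seeds are drawn (structured seed sequences such as
#'   arithmetic progressions produce measurably correlated
#'   Mersenne-Twister streams, so per-trip seeds are sampled instead).
#' @param out_dir if non-`NULL`, each session is written under
#'   `out_dir/<participant>_<session>/`.
#' @return A list of `"dsr_session"` objects (invisible when written).
#' @export
simulate_cohort <- function(n_participants = 40, n_sessions = 2,
                            scenario = scenario_config(),
                            response = response_config(),
                            base_seed = 1L, out_dir = NULL) {
  cells <- expand.grid(session = sprintf("s%d", seq_len(n_sessions)),
                       participant = sprintf("p%02d", seq_len(n_participants)),
                       stringsAsFactors = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(base_seed)
  trip_seeds <- sample.int(2147483646L, nrow(cells))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rc <- response
    rc$seed <- trip_seeds[i]
    s <- simulate_session(scenario, rc, participant = cells$participant[i],
                          session = cells$session[i])
    if (!is.null(out_dir))
      write_session(file.path(out_dir, paste0(cells$participant[i], "_",
                                              cells$session[i])), s)
    out[[i]] <- s
  }
  names(out) <- paste0(cells$participant, "_", cells$session)
  if (is.null(out_dir)) out else invisible(out)
}
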