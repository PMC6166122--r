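#' Z-standardize a series over a stated scope
#'
#' `(x - mean) / sd` using the sample SD over all non-missing values of
#' the scope, giving mean 0 and SD 1 over that scope. A constant series
#' (SD = 0) maps to all zeros with the `"degenerate"` attribute set;
#' missing values propagate.
#'
#' @param x numeric vector (one scope: a sequence, a whole trip, ...).
#' @param scope label recorded on the result
#'   (`"sequence"`, `"trip"`, `"sliding-window"`).
#' @return Numeric vector of z-values with attributes `scope` and
#'   `degenerate`.
#' @export
zscore <- function(x, scope = "sequence") {
  ok <- !is.na(x)
  if (sum(ok) < 2L)
    stop("zscore needs at least 2 non-missing values")
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  degenerate <- s == 0
  z <- if (degenerate) ifelse(ok, 0, NA_real_) else (x - m) / s
  attr(z, "scope") <- scope
  attr(z, "degenerate") <- degenerate
  z
}

# centered moving-average over +/- half_window ticks, ignoring NA
moving_average <- function(x, half_window) {
  n <- length(x)
  w <- 2L * half_window + 1L
  v <- ifelse(is.na(x), 0, x)
  k <- as.numeric(!is.na(x))
  pad <- numeric(half_window)
  cs_v <- cumsum(c(pad, v, pad))
  cs_k <- cumsum(c(pad, k, pad))
  i <- seq_len(n)
  sums <- cs_v[i + w - 1L] - c(0, cs_v)[i + w - 1L - (w - 1L)]
  cnts <- cs_k[i + w - 1L] - c(0, cs_k)[i + w - 1L - (w - 1L)]
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

#' Preprocess binocular pupil diameters
#'
#' Per-tick mean of the available eyes (missing only where both eyes are
#' missing, e.g. inside blinks), then a centered moving average over
#' +/-300 ms (+/-18 ticks at 60 Hz) that ignores missing samples rather
#' than interpolating through them.
#'
#' @param left,right pupil diameters (mm) on the master timeline.
#' @param rate master rate in Hz (default 60).
#' @param smooth_s half-width of the moving average in seconds
#'   (default 0.3).
#' @return Smoothed single pupil-diameter series (mm).
#' @export
pupil_preprocess <- function(left, right, rate = 60, smooth_s = 0.3) {
  stopifnot(length(left) == length(right))
  both <- cbind(left, right)
  mono <- rowMeans(both, na.rm = TRUE)
  mono[is.nan(mono)] <- NA_real_
  moving_average(mono, as.integer(round(smooth_s * rate)))
}

#' Mean HSL lightness of a video frame
#'
#' Per-pixel lightness `L = (max(R,G,B) + min(R,G,B)) / 2` on a `[0, 1]`
#' scale, averaged over all pixels.
#'
#' @param frame an `n x 3` matrix of R,G,B values in `[0, 1]`, or an
#'   `h x w x 3` array.
#' @return Scalar mean lightness in `[0, 1]`.
#' @export
frame_luminance <- function(frame) {
  if (is.array(frame) && length(dim(frame)) == 3L)
    frame <- cbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
                   as.vector(frame[, , 3]))
  if (!is.matrix(frame) || ncol(frame) != 3L || nrow(frame) == 0L)
    stop("frame must be a non-empty n x 3 RGB matrix or h x w x 3 array")
  l <- (pmax(frame[, 1], frame[, 2], frame[, 3]) +
          pmin(frame[, 1], frame[, 2], frame[, 3])) / 2
  mean(l)
}

#' Luminance-adjust a pupil z-series
#'
#' Subtracts the whole-trip luminance z-scores from the per-sequence
#' pupil z-scores, elementwise, to remove the ambient-light component of
#' pupil size (the looming white truck brightens the scene exactly when
#' discomfort is expected).
#'
#' @param pupil_z per-sequence pupil z-values on the master timeline.
#' @param luminance_z whole-trip luminance z-values on the same ticks.
#' @return `pupil_z - luminance_z`.
#' @export
luminance_adjust <- function(pupil_z, luminance_z) {
  if (length(pupil_z) != length(luminance_z))
    stop("pupil_z and luminance_z must have the same length")
  as.numeric(pupil_z) - as.numeric(luminance_z)
}

#' Blink rate over a window
#'
#' Number of blink onsets falling in `[start, end)` divided by the
#' window duration.
#'
#' @param onsets sorted blink onset times (s).
#' @param start,end window bounds (s), `end > start`.
#' @return Events per second.
#' @export
blink_rate <- function(onsets, start, end) {
  if (end <= start) stop("blink_rate: window must have positive duration")
  sum(onsets >= start & onsets < end) / (end - start)
}

#' Running interblink timer
#'
#' At each master tick, seconds elapsed since the latest blink onset at
#' or before that tick (the timer resets to zero at each blink start;
#' blink duration is not excluded). Before the first blink the timer
#' counts from the window start and those ticks are flagged.
#'
#' @param onsets sorted blink onset times (s).
#' @param timestamps master-timeline tick times (s).
#' @return Numeric series (s) with logical attribute `pre_first`.
#' @export
interblink_timer <- function(onsets, timestamps) {
  idx <- findInterval(timestamps, onsets)
  out <- ifelse(idx >= 1L, timestamps - onsets[pmax(idx, 1L)],
                timestamps - timestamps[1])
  attr(out, "pre_first") <- idx < 1L
  out
}

#' RMSSD from interbeat intervals
#'
#' Root mean square of successive differences of the per-beat interbeat
#' intervals within a window. Because the band logs the last beat value
#' at a 10 Hz cadence, consecutive duplicate entries are collapsed first
#' to recover the per-beat series.
#'
#' @param ibi interbeat intervals in seconds, in time order (raw 10 Hz
#'   log or per-beat values).
#' @param collapse collapse consecutive duplicates first (default TRUE).
#' @return RMSSD in seconds; `NA` with attribute `short_window = TRUE`
#'   when fewer than 3 beats remain.
#' @export
rmssd <- function(ibi, collapse = TRUE) {
  ibi <- ibi[!is.na(ibi)]
  if (collapse && length(ibi) > 1L)
    ibi <- ibi[c(TRUE, diff(ibi) != 0)]
  if (length(ibi) < 3L) {
    out <- NA_real_
    attr(out, "short_window") <- TRUE
    return(out)
  }
  d <- diff(ibi)
  out <- sqrt(mean(d^2))
  attr(out, "short_window") <- FALSE
  out
}

#' Convert skin resistance to skin conductance
#'
#' The band logs skin resistance in kiloohm; conductance in
#' microsiemens is `1000 / resistance`. Non-positive resistances become
#' missing with a warning.
#'
#' @param resistance_kohm skin resistance (kOhm).
#' @return Skin conductance level (microsiemens).
#' @export
scl_convert <- function(resistance_kohm) {
  bad <- !is.na(resistance_kohm) & resistance_kohm <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive resistance value(s) set to missing")
    resistance_kohm[bad] <- NA_real_
  }
  1000 / resistance_kohm
}

#' Movement-artifact mask from band accelerometer and gyroscope
#'
#' TRUE where the accelerometer magnitude deviates from 1 g by more than
#' `accel_threshold` or the gyroscope magnitude exceeds
#' `gyro_threshold`, dilated by +/-`dilation` seconds. Masked samples of
#' a wrist channel (SCL) should be treated as missing: masking removes
#' values, never alters them.
#'
#' @param accel accelerometer magnitude (g) on the master timeline.
#' @param gyro gyroscope magnitude (deg/s) on the same ticks.
#' @param timestamps tick times (s).
#' @param accel_threshold deviation from 1 g flagged as movement
#'   (default 0.15 g).
#' @param gyro_threshold gyro magnitude flagged as movement
#'   (default 60 deg/s).
#' @param dilation half-width of the dilation window in seconds
#'   (default 0.5).
#' @return Logical mask, TRUE = movement artifact.
#' @export
movement_mask <- function(accel, gyro, timestamps,
                          accel_threshold = 0.15, gyro_threshold = 60,
                          dilation = 0.5) {
  stopifnot(length(accel) == length(timestamps),
            length(gyro) == length(timestamps))
  raw <- (!is.na(accel) & abs(accel - 1) > accel_threshold) |
    (!is.na(gyro) & abs(gyro) > gyro_threshold)
  if (!any(raw) || dilation <= 0) return(raw)
  hits <- timestamps[raw]
  mask <- rep(FALSE, length(timestamps))
  for (h in hits)
    mask <- mask | (timestamps >= h - dilation & timestamps <= h + dilation)
  mask
}

#' Remove a per-sequence linear trend
#'
#' Least-squares line fit of value on time over one sequence; the result
#' is `value - fit` (residuals), which has zero mean and zero fitted
#' slope. Used to strip the tonic skin-conductance drift that accrues as
#' the participant warms up.
#'
#' @param x series to detrend (z-values or raw), `NA` allowed.
#' @param timestamps matching time vector (s).
#' @return Residual series, `NA` preserved.
#' @export
detrend_linear <- function(x, timestamps) {
  stopifnot(length(x) == length(timestamps))
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("detrend_linear needs at least 3 non-missing values")
  if (stats::sd(timestamps[ok]) == 0)
    stop("detrend_linear: degenerate fit (constant time)")
  fit <- stats::lm.fit(cbind(1, timestamps[ok]), x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- fit$residuals
  out
}

#' Displacement from sequence start
#'
#' Position change relative to the first tick of the sequence, so every
#' sequence starts at exactly zero regardless of the absolute marker
#' position. If the first value is missing the first non-missing value
#' is used as reference and the result is flagged.
#'
#' @param x position series (mm).
#' @return Displacement series (mm) with logical attribute
#'   `ref_shifted`.
#' @export
displacement_from_start <- function(x) {
  if (!length(x)) stop("displacement_from_start: empty series")
  ref_shifted <- is.na(x[1])
  ref <- x[which(!is.na(x))[1]]
  if (is.na(ref)) stop("displacement_from_start: all values missing")
  out <- x - ref
  attr(out, "ref_shifted") <- ref_shifted
  out
}
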