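#' Sensor channel
#'
#' A single timestamped sensor stream: strictly increasing timestamps in
#' seconds plus one value per sample, with a native sampling rate and unit.
#' Values may be `NA` (e.g. pupil samples inside blinks).
#'
#' @param name channel name (scalar character).
#' @param timestamp_s numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param value numeric vector, same length as `timestamp_s`; `NA` allowed.
#' @param rate nominal native sampling rate in Hz.
#' @param unit measurement unit (free text, e.g. `"bpm"`, `"kOhm"`).
#' @return An object of class `"dsr_channel"`.
#' @export
channel <- function(name, timestamp_s, value, rate, unit = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(timestamp_s), is.numeric(value),
            length(timestamp_s) == length(value),
            is.numeric(rate), length(rate) == 1L, rate > 0)
  if (length(timestamp_s) > 1L && any(diff(timestamp_s) <= 0))
    stop("channel '", name, "': timestamps must be strictly increasing")
  structure(
    list(name = name, rate = rate, unit = unit,
         data = data.frame(timestamp_s = as.numeric(timestamp_s),
                           value = as.numeric(value))),
    class = "dsr_channel")
}

#' Event stream
#'
#' Discrete events (e.g. eye blinks) with onset and duration in seconds.
#'
#' @param name stream name.
#' @param onset_s numeric vector of event onsets, strictly increasing.
#' @param duration_s numeric vector of event durations (seconds), `>= 0`.
#' @return An object of class `"dsr_events"`.
#' @export
event_stream <- function(name, onset_s, duration_s) {
  stopifnot(is.character(name), length(name) == 1L,
            length(onset_s) == length(duration_s))
  if (length(onset_s) > 1L && any(diff(onset_s) <= 0))
    stop("event stream '", name, "': onsets must be strictly increasing")
  if (length(duration_s) && any(duration_s < 0))
    stop("event stream '", name, "': durations must be >= 0")
  structure(
    list(name = name,
         data = data.frame(onset_s = as.numeric(onset_s),
                           duration_s = as.numeric(duration_s))),
    class = "dsr_events")
}

#' @export
print.dsr_channel <- function(x, ...) {
  n <- nrow(x$data)
  span <- if (n) sprintf("%.2f-%.2f s", x$data$timestamp_s[1],
                         x$data$timestamp_s[n]) else "empty"
  cat(sprintf("<channel '%s'> %d samples @ %g Hz [%s] (%s)\n",
              x$name, n, x$rate, x$unit, span))
  invisible(x)
}

#' @export
print.dsr_events <- function(x, ...) {
  cat(sprintf("<event stream '%s'> %d events\n", x$name, nrow(x$data)))
  invisible(x)
}

#' @export
print.dsr_session <- function(x, ...) {
  cat(sprintf("<session> participant %s, session %s, seed %s\n",
              x$manifest$participant, x$manifest$session,
              x$manifest$seed))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (length(x$events))
    cat("  events:  ", paste(names(x$events), collapse = ", "), "\n")
  invisible(x)
}
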