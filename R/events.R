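#' Extract discomfort intervals from the handset channel
#'
#' A discomfort interval runs from the start of pressing the handset
#' lever until its release, independent of magnitude: maximal runs of
#' samples above `press_threshold`. Runs separated by less than
#' `merge_gap` are merged (guards against release flutter); runs shorter
#' than `min_duration` are dropped (quantisation noise).
#'
#' @param handset a `"dsr_recording"` (its `handset` column is used), a
#'   `"dsr_channel"`, or a numeric vector (then supply `timestamp_s`).
#' @param press_threshold press detection level as a fraction of full
#'   scale (default 0.02).
#' @param merge_gap merge runs closer than this many seconds
#'   (default 0.3).
#' @param min_duration drop runs shorter than this many seconds
#'   (default 0.5).
#' @param timestamp_s timestamps when `handset` is a bare vector.
#' @return A data frame of class `"dsr_intervals"`:
#'   `onset, offset, duration, peak`, ordered by onset. Zero rows when
#'   nothing was pressed.
#' @export
extract_intervals <- function(handset, press_threshold = 0.02,
                              merge_gap = 0.3, min_duration = 0.5,
                              timestamp_s = NULL) {
  if (inherits(handset, "dsr_recording")) {
    timestamp_s <- handset$timestamp_s
    handset <- handset$handset
  } else if (inherits(handset, "dsr_channel")) {
    timestamp_s <- handset$data$timestamp_s
    handset <- handset$data$value
  }
  stopifnot(is.numeric(handset), length(handset) == length(timestamp_s))
  if (any(handset < 0, na.rm = TRUE))
    stop("handset values must be >= 0")

  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), peak = numeric(0))
  class(empty) <- c("dsr_intervals", "data.frame")
  above <- !is.na(handset) & handset > press_threshold
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$onset <- timestamp_s[runs$start]
  runs$offset <- timestamp_s[runs$end]

  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      j <- nrow(merged)
      if (runs$onset[i] - merged$offset[j] < merge_gap) {
        merged$offset[j] <- runs$offset[i]
        merged$end[j] <- runs$end[i]
      } else merged <- rbind(merged, runs[i, ])
    }
  }
  merged$duration <- merged$offset - merged$onset
  merged <- merged[merged$duration >= min_duration, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  merged$peak <- vapply(seq_len(nrow(merged)), function(i)
    max(handset[merged$start[i]:merged$end[i]], na.rm = TRUE), 0)
  out <- merged[, c("onset", "offset", "duration", "peak")]
  rownames(out) <- NULL
  class(out) <- c("dsr_intervals", "data.frame")
  out
}

#' Descriptive statistics of extracted intervals
#'
#' Count, mean and SD of durations — the per-run bookkeeping quoted in
#' every aggregate chart caption.
#'
#' @param intervals a `"dsr_intervals"` table (or an rbind of several).
#' @return `list(n, mean_duration, sd_duration)`.
#' @export
interval_stats <- function(intervals) {
  list(n = nrow(intervals),
       mean_duration = mean(intervals$duration),
       sd_duration = stats::sd(intervals$duration))
}

#' Build an event-locked sequence around one discomfort interval
#'
#' A sequence is the discomfort interval plus the 10 s before the press
#' onset and the 10 s after release, with all master-timeline channel
#' slices attached. Windows hitting a trip boundary are clipped and
#' flagged; a neighbouring press inside the pre/post windows is kept (the
#' three-per-trip design makes overlap rare) and flagged.
#'
#' @param rec a `"dsr_recording"`.
#' @param interval one row of a `"dsr_intervals"` table (or a list with
#'   `onset` and `offset`).
#' @param window pre/post window length in seconds (default 10).
#' @param all_intervals optional full interval table used to flag
#'   neighbour-press overlap.
#' @return A list of class `"dsr_sequence"`: the interval, the sliced
#'   recording rows (`data`), logical phase masks `pre`, `during`,
#'   `post`, and `truncated_pre/post`, `overlap` flags.
#' @export
build_sequence <- function(rec, interval, window = 10,
                           all_intervals = NULL) {
  stopifnot(inherits(rec, "dsr_recording"))
  t <- rec$timestamp_s
  t0 <- t[1]; t_end <- t[length(t)]
  on <- interval$onset; off <- interval$offset
  if (is.na(on) || is.na(off) || off <= on)
    stop("invalid interval: need offset > onset")
  if (on < t0 || off > t_end)
    stop("interval [", on, ", ", off, "] outside recording span [",
         t0, ", ", t_end, "]")

  lo <- max(on - window, t0)
  hi <- min(off + window, t_end)
  keep <- t >= lo & t <= hi
  data <- as.data.frame(rec)[keep, , drop = FALSE]
  rownames(data) <- NULL
  ts <- data$timestamp_s

  overlap <- FALSE
  if (!is.null(all_intervals) && nrow(all_intervals) > 1) {
    others <- all_intervals[all_intervals$onset != on, , drop = FALSE]
    overlap <- any(others$onset <= hi & others$offset >= lo)
  }
  structure(list(
    interval = list(onset = on, offset = off, duration = off - on,
                    peak = interval$peak),
    window = window,
    data = data,
    pre = ts >= lo & ts < on,
    during = ts >= on & ts <= off,
    post = ts > off & ts <= hi,
    truncated_pre = (on - window) < t0,
    truncated_post = (off + window) > t_end,
    overlap = overlap,
    participant = attr(rec, "participant"),
    session = attr(rec, "session")),
    class = "dsr_sequence")
}

#' Resample one sequence channel onto the 0-300% percent scale
#'
#' Time normalisation for variable-duration episodes: slices 1-100 cover
#' the 10 s pre window (0.1 s each), 101-200 the discomfort interval
#' (duration/100 each), 201-300 the 10 s post window (0.1 s each). Each
#' slice value is the mean of the non-missing master samples whose
#' timestamps fall in the slice's half-open `[start, end)` span. Slices
#' left empty (possible when the interval is shorter than 100 master
#' ticks) are filled by linear interpolation between the nearest
#' non-empty slices and flagged; slices beyond a truncated trip boundary
#' stay missing.
#'
#' @param seq a `"dsr_sequence"`.
#' @param channel channel column name (or a numeric vector aligned with
#'   `seq$data`, e.g. an already-standardized series).
#' @param values optional numeric vector overriding the stored column.
#' @return A list of class `"dsr_profile"`: `channel`, `values` (length
#'   300), `interpolated` and `missing` masks, `slice_width` per phase,
#'   and the interval metadata.
#' @export
percent_resample <- function(seq, channel, values = NULL) {
  stopifnot(inherits(seq, "dsr_sequence"))
  if (is.null(values)) {
    if (!is.character(channel) || !channel %in% names(seq$data))
      stop("channel '", channel, "' not present in sequence")
    values <- seq$data[[channel]]
    cname <- channel
  } else {
    stopifnot(length(values) == nrow(seq$data))
    cname <- if (is.character(channel)) channel else "custom"
  }
  on <- seq$interval$onset; off <- seq$interval$offset
  w <- seq$window
  ts <- seq$data$timestamp_s

  edges <- c(seq(on - w, on, length.out = 101)[1:100],
             seq(on, off, length.out = 101)[1:100],
             seq(off, off + w, length.out = 101))
  idx <- findInterval(ts, edges, left.open = FALSE)
  ok <- idx >= 1L & idx <= 300L & !is.na(values)
  sums <- tabulate0(idx[ok], values[ok], 300L)
  cnt <- tabulate(idx[ok], nbins = 300L)
  vals <- ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)

  # slices outside the recorded span (boundary truncation) stay missing
  t0 <- ts[1]; t_end <- ts[length(ts)]
  out_of_span <- edges[1:300] >= t_end | edges[2:301] <= t0
  fillable <- cnt == 0 & !out_of_span
  interpolated <- fillable & FALSE
  if (any(fillable) && any(cnt > 0)) {
    known <- which(cnt > 0)
    fill <- stats::approx(known, vals[known], xout = which(fillable),
                          rule = 2)$y
    vals[fillable] <- fill
    interpolated <- fillable
  }
  vals[out_of_span] <- NA_real_

  structure(list(channel = cname, values = vals,
                 interpolated = interpolated,
                 missing = is.na(vals),
                 slice_width = c(pre = w / 100,
                                 during = (off - on) / 100,
                                 post = w / 100),
                 interval = seq$interval,
                 participant = seq$participant,
                 session = seq$session),
            class = "dsr_profile")
}

# groupwise sums into exactly n bins (base tapply-free helper)
tabulate0 <- function(bin, x, n) {
  out <- numeric(n)
  agg <- rowsum(x, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
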