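#' Read a session directory
#'
#' Loads the manifest plus every channel and event-stream CSV it lists.
#' Malformed rows (non-numeric fields) are skipped with a warning and
#' counted; a channel listed in the manifest whose file is absent is a
#' hard error.
#'
#' @param dir session directory containing `manifest.yaml`.
#' @return A `"dsr_session"` with `manifest`, `channels` and `events`;
#'   the number of rows skipped per file is in the `"skipped"` attribute.
#' @export
read_session <- function(dir) {
  man_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(man_path))
    stop("no manifest.yaml in ", dir)
  man <- yaml::read_yaml(man_path)
  skipped <- integer(0)

  read_two_col <- function(path, cols) {
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = character(0))
    if (!all(cols %in% names(df)))
      stop("file ", path, " lacks columns ", paste(cols, collapse = ","))
    a <- suppressWarnings(as.numeric(df[[cols[1]]]))
    b <- suppressWarnings(as.numeric(df[[cols[2]]]))
    # "NA" in the value column is a legitimate missing sample, not a bad row
    bad <- is.na(a) | (is.na(b) & df[[cols[2]]] != "NA")
    if (any(bad)) {
      warning(sum(bad), " unparseable row(s) skipped in ", basename(path))
      a <- a[!bad]; b <- b[!bad]
    }
    skipped[basename(path)] <<- sum(bad)
    list(a = a, b = b)
  }

  channels <- list()
  for (entry in man$channels) {
    path <- file.path(dir, entry$file)
    if (!file.exists(path))
      stop("channel '", entry$name, "' listed in manifest but file ",
           entry$file, " is missing")
    xy <- read_two_col(path, c("timestamp_s", "value"))
    channels[[entry$name]] <- channel(entry$name, xy$a, xy$b,
                                      entry$rate, entry$unit)
  }
  events <- list()
  for (entry in man$events) {
    path <- file.path(dir, entry$file)
    if (!file.exists(path))
      stop("event stream '", entry$name, "' listed in manifest but file ",
           entry$file, " is missing")
    xy <- read_two_col(path, c("onset_s", "duration_s"))
    events[[entry$name]] <- event_stream(entry$name, xy$a, xy$b)
  }
  out <- structure(list(manifest = man, channels = channels,
                        events = events), class = "dsr_session")
  attr(out, "skipped") <- skipped
  out
}

# nearest-previous (sample-and-hold) lookup of a channel on master ticks
hold_join <- function(ch, master_t) {
  idx <- findInterval(master_t, ch$data$timestamp_s)
  out <- rep(NA_real_, length(master_t))
  has <- idx >= 1L
  out[has] <- ch$data$value[idx[has]]
  out
}

#' Join all channels onto the 60 Hz master timeline
#'
#' Sample-and-hold synchronisation: each master tick carries, for every
#' channel, the most recent native sample at or before that tick
#' (missing before a channel's first sample). Event streams are joined as
#' a 0/1 onset-indicator column plus a running since-last-event timer
#' column (`<name>_onset`, `<name>_timer`).
#'
#' @param session a `"dsr_session"`, or a named list of channels via
#'   `channels =`/`events =`.
#' @param master name of the channel whose timestamps define the master
#'   timeline (default `"handset"`, the 60 Hz simulator clock).
#' @param channels,events used when `session` is `NULL`.
#' @return A `"dsr_recording"` data frame: `timestamp_s` plus one column
#'   per channel/event feature; units, the manifest and the event streams
#'   travel in attributes.
#' @export
resample_to_master <- function(session = NULL, master = "handset",
                               channels = NULL, events = NULL) {
  if (!is.null(session)) {
    stopifnot(inherits(session, "dsr_session"))
    channels <- session$channels
    events <- session$events
  }
  if (is.null(events)) events <- list()
  if (!master %in% names(channels))
    stop("master channel '", master, "' not present")
  master_t <- channels[[master]]$data$timestamp_s
  if (length(master_t) > 2L) {
    dt <- diff(master_t)
    if (max(dt) - min(dt) > 2e-3)          # 1 ms jitter tolerance per edge
      warning("master timestamps deviate from a uniform grid")
  }

  rec <- data.frame(timestamp_s = master_t)
  units <- character(0)
  for (nm in names(channels)) {
    vals <- hold_join(channels[[nm]], master_t)
    if (all(is.na(vals)))
      warning("channel '", nm, "' has no samples before trip end; ",
              "all-missing column")
    rec[[nm]] <- vals
    units[nm] <- channels[[nm]]$unit
  }
  for (nm in names(events)) {
    on <- events[[nm]]$data$onset_s
    idx <- findInterval(on, master_t)               # tick at/before onset
    ind <- numeric(length(master_t))
    ind[idx[idx >= 1L]] <- 1
    rec[[paste0(nm, "_onset")]] <- ind
    rec[[paste0(nm, "_timer")]] <- interblink_timer(on, master_t)
    units[paste0(nm, "_onset")] <- "indicator"
    units[paste0(nm, "_timer")] <- "s"
  }
  attr(rec, "units") <- units
  attr(rec, "events") <- events
  if (!is.null(session)) {
    attr(rec, "manifest") <- session$manifest
    attr(rec, "participant") <- session$manifest$participant
    attr(rec, "session") <- session$manifest$session
  }
  class(rec) <- c("dsr_recording", "data.frame")
  rec
}

#' Write a recording as one wide CSV
#'
#' `timestamp_s,<channel...>` with one row per master tick.
#'
#' @param rec a `"dsr_recording"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}
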