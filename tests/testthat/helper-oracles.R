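# independent brute-force oracles; deliberately naive, never shared with
# the implementation paths they check

oracle_hold <- function(native_t, native_v, master_t) {
  vapply(master_t, function(tt) {
    i <- which(native_t <= tt)
    if (!length(i)) NA_real_ else native_v[max(i)]
  }, numeric(1))
}

oracle_moving_avg <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

oracle_rmssd <- function(ibi) sqrt(mean(diff(ibi)^2))

oracle_percent_slices <- function(ts, vals, on, off, w = 10) {
  edges <- c(seq(on - w, on, length.out = 101)[1:100],
             seq(on, off, length.out = 101)[1:100],
             seq(off, off + w, length.out = 101))
  vapply(1:300, function(i) {
    inside <- ts >= edges[i] & ts < edges[i + 1] & !is.na(vals)
    if (!any(inside)) NA_real_ else mean(vals[inside])
  }, numeric(1))
}

oracle_sliding_z <- function(x, ts, len, onset, min_n = 5) {
  vapply(seq_along(x), function(i) {
    inw <- ts >= ts[i] - onset - len & ts <= ts[i] - onset & !is.na(x)
    w <- x[inw]
    if (length(w) < min_n || is.na(x[i])) return(NA_real_)
    s <- stats::sd(w)
    if (s < 1e-12) return(0)
    (x[i] - mean(w)) / s
  }, numeric(1))
}

oracle_detrend <- function(x, ts) {
  ok <- !is.na(x)
  X <- cbind(1, ts[ok])
  beta <- solve(t(X) %*% X, t(X) %*% x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- x[ok] - X %*% beta
  out
}

oracle_intervals <- function(ts, v, thr, merge_gap, min_dur) {
  above <- which(!is.na(v) & v > thr)
  if (!length(above)) return(data.frame(onset = numeric(0),
                                        offset = numeric(0)))
  brk <- c(0, which(diff(above) > 1), length(above))
  runs <- data.frame(
    onset = ts[above[brk[-length(brk)] + 1]],
    offset = ts[above[brk[-1]]])
  i <- 1
  while (i < nrow(runs)) {
    if (runs$onset[i + 1] - runs$offset[i] < merge_gap) {
      runs$offset[i] <- runs$offset[i + 1]
      runs <- runs[-(i + 1), ]
    } else i <- i + 1
  }
  runs[runs$offset - runs$onset >= min_dur, , drop = FALSE]
}
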