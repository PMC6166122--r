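#' Aggregate percent profiles across sequences
#'
#' Per-slice mean of the z-values over all contributing sequences with a
#' pointwise 95% confidence interval,
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)`. No multiplicity correction is
#' applied: the band supports comparing single points in time, not the
#' curve as a whole. Slices missing in every profile stay missing.
#'
#' @param profiles list of `"dsr_profile"` objects for one channel.
#' @param conf confidence level (default 0.95).
#' @return A data frame of class `"dsr_aggregate"`:
#'   `channel, slice, mean, n, ci_lo, ci_hi` (300 rows).
#' @export
aggregate_profiles <- function(profiles, conf = 0.95) {
  if (length(profiles) < 2L)
    stop("aggregate_profiles needs at least 2 profiles")
  chan <- unique(vapply(profiles, function(p) p$channel, ""))
  if (length(chan) != 1L)
    stop("profiles mix channels: ", paste(chan, collapse = ", "))
  mat <- vapply(profiles, function(p) p$values, numeric(300))
  n <- rowSums(!is.na(mat))
  m <- ifelse(n > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  s <- apply(mat, 1, stats::sd, na.rm = TRUE)
  half <- ifelse(n > 1,
                 stats::qt(1 - (1 - conf) / 2, pmax(n - 1, 1)) *
                   s / sqrt(pmax(n, 1)),
                 NA_real_)
  out <- data.frame(channel = chan, slice = 1:300, mean = m, n = n,
                    ci_lo = m - half, ci_hi = m + half)
  class(out) <- c("dsr_aggregate", "data.frame")
  out
}

#' Non-overlap significance heuristic between two slices
#'
#' TRUE when the two pointwise 95% CIs are disjoint, which reads as a
#' significant mean difference at p < 0.01. A shared endpoint counts as
#' overlap (closed intervals). Symmetric in its arguments.
#'
#' @param agg a `"dsr_aggregate"`.
#' @param slice_i,slice_j slice indices in 1..300.
#' @return Logical scalar.
#' @export
nonoverlap_significant <- function(agg, slice_i, slice_j) {
  pick <- function(k) {
    row <- agg[agg$slice == k, ]
    if (nrow(row) != 1L || is.na(row$ci_lo) || is.na(row$ci_hi))
      stop("slice ", k, " missing or without a CI")
    c(row$ci_lo, row$ci_hi)
  }
  a <- pick(slice_i); b <- pick(slice_j)
  a[2] < b[1] || b[2] < a[1]
}

#' Phase summary table
#'
#' Pre/during/post means of a per-interval scalar metric (blink rate in
#' events per s, RMSSD in s) across sequences, with pointwise t-based
#' CIs. Descriptive only.
#'
#' @param summaries data frame with columns
#'   `sequence_id, metric, pre, during, post` (one row per sequence and
#'   metric), e.g. stacked outputs of [analyze_recording()].
#' @param conf confidence level (default 0.95).
#' @return Data frame `metric, phase, mean, n, ci_lo, ci_hi`.
#' @export
phase_table <- function(summaries, conf = 0.95) {
  stopifnot(all(c("metric", "pre", "during", "post") %in% names(summaries)))
  rows <- list()
  for (met in unique(summaries$metric)) {
    sub <- summaries[summaries$metric == met, ]
    for (ph in c("pre", "during", "post")) {
      v <- sub[[ph]]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n < 2L)
        stop("phase_table needs at least 2 summaries per metric")
      half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(v) / sqrt(n)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, phase = ph, mean = mean(v), n = n,
        ci_lo = mean(v) - half, ci_hi = mean(v) + half)
    }
  }
  out <- do.call(rbind, rows)
  out$phase <- factor(out$phase, levels = c("pre", "during", "post"))
  rownames(out) <- NULL
  out
}

#' Plot an aggregate profile with its CI band
#'
#' Mean curve over the 0-300% axis with the pointwise 95% CI as a shaded
#' band; vertical guides mark the interval onset (100%) and release
#' (200%). Requires ggplot2.
#'
#' @param agg a `"dsr_aggregate"`.
#' @param ylab y-axis label.
#' @return A ggplot object.
#' @export
plot_aggregate <- function(agg, ylab = "z-score") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_aggregate requires ggplot2")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$slice)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "#ffb3b3", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "#1f4e9c",
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(100, 200), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "sequence time (%)", y = ylab,
                  title = unique(agg$channel)) +
    ggplot2::theme_minimal()
}
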