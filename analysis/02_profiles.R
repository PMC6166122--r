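#!/usr/bin/env Rscript

# Step 2 — event-locked analysis of the recorded sessions.
#
# Reads every session directory written by 01_simulate.R, joins all
# channels onto the 60 Hz master timeline by sample-and-hold, extracts
# the discomfort intervals from the handset channel, applies every
# per-parameter transform (luminance-adjusted pupil z, interblink-timer
# z, HR z, movement-masked + detrended SCL z, shoulder-z displacement z,
# back-pressure z), percent-resamples each sequence onto the 0-300%
# axis, and aggregates across sequences into mean curves with pointwise
# 95% CI bands plus the blink-rate / RMSSD phase table.

library(discomfortr)

session_dirs <- list.dirs("results/sessions", recursive = FALSE)
stopifnot(length(session_dirs) > 0)
sessions <- lapply(session_dirs, read_session)

res <- analyze_cohort(sessions)

cat(sprintf("extracted %d discomfort intervals (M = %.2f s, SD = %.2f s)\n",
            res$stats$n, res$stats$mean_duration, res$stats$sd_duration))

# per-sequence interval table
write.csv(res$intervals, "results/intervals.csv", row.names = FALSE)

# 300-slice aggregate curves, one row per channel x slice
agg <- do.call(rbind, res$aggregates)
write.csv(agg, "results/aggregates.csv", row.names = FALSE)

# blink-rate and RMSSD phase summaries
write.csv(res$phase_table, "results/phase_table.csv", row.names = FALSE)

cat("\nphase table (pre / during / post):\n")
print(res$phase_table, digits = 3)

cat("\nduring-phase minus pre-phase aggregate z (expected directions):\n")
for (nm in names(res$aggregates)) {
  m <- res$aggregates[[nm]]$mean
  cat(sprintf("  %-14s %+.2f\n", nm,
              mean(m[101:200], na.rm = TRUE) - mean(m[1:100], na.rm = TRUE)))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  for (nm in names(res$aggregates)) {
    p <- plot_aggregate(res$aggregates[[nm]])
    ggplot2::ggsave(file.path("results", paste0("profile_", nm, ".png")),
                    p, width = 6, height = 3.2, dpi = 120)
  }
  cat("\nwrote profile figures to results/profile_*.png\n")
}
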