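#!/usr/bin/env Rscript

# Step 3 — prototype online discomfort detector.
#
# Runs the causal sliding-window z-score detector over every session
# (heart rate at -0.3 SD, pupil / shoulder-z / back pressure at +/-2 SD,
# all four channels required to agree, 5 s refractory; baselines 10 s
# ending 3 s ago and 5 s ending 5 s ago) and scores the detections
# against the handset-extracted intervals of the same session.

library(discomfortr)

session_dirs <- list.dirs("results/sessions", recursive = FALSE)
stopifnot(length(session_dirs) > 0)
sessions <- lapply(session_dirs, read_session)

cfg <- detector_config()
eval_tab <- detect_cohort(sessions, cfg)
eval_tab$session <- basename(session_dirs)
write.csv(eval_tab, "results/detection_eval.csv", row.names = FALSE)

cat("per-session detector evaluation:\n")
print(eval_tab, digits = 3)
cat(sprintf("\noverall: hit rate %.2f, %.2f false alarms per trip, median latency %.2f s\n",
            weighted.mean(eval_tab$hit_rate, eval_tab$n_truth, na.rm = TRUE),
            mean(eval_tab$false_alarms),
            median(eval_tab$median_latency, na.rm = TRUE)))
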