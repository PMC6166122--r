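Package: discomfortr
Title: Event-Locked Analysis of Physiological Discomfort Responses in
    Automated Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-sensor recordings of passenger
    discomfort during automated close-approach driving manoeuvres.
    Implements event-locked interval extraction from a continuous handset
    report, sample-and-hold synchronisation of multi-rate sensor streams
    onto a 60 Hz master timeline, percent-scale (0-300%) time
    normalisation of variable-duration episodes, per-parameter
    preprocessing (binocular pupil averaging with luminance correction,
    interblink timing, RMSSD heart-rate variability from interbeat
    intervals, skin-conductance conversion with movement-artifact masking
    and linear detrending, displacement-from-start body motion),
    cross-sequence aggregation with pointwise 95% confidence bands, and a
    prototype sliding-window z-score detector with weighted-evidence
    fusion. Includes a seed-controlled synthetic session generator that
    emulates the driving scenario, handset behaviour and all sensor
    channels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
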