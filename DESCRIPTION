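Package: gazesa
Title: Gaze-Based Situational-Awareness Metrics with Expert-Baseline Alerting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for screen-mounted eye-tracking recordings of
    monitoring tasks: velocity-threshold (I-VT) fixation detection, percent
    fixation duration and count metrics over an area-of-interest (AOI)
    partition with windowed critical-interval summaries, pupillogram
    preprocessing (gap interpolation, Savitzky-Golay smoothing, binocular
    averaging, baseline normalisation), rank-based group comparison
    (Kruskal-Wallis omnibus with Dunn-Bonferroni pairwise post hoc), and an
    expert-baseline attention-deviation alerting framework for real-time
    operation centres.  A synthetic gaze-data generator emulates expert and
    novice attention profiles in a five-minute, 300 Hz monitoring scenario
    with an anomaly window, so every pipeline stage is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
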