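# gazesa

Gaze-based situational-awareness metrics with expert-baseline alerting.

Operators who monitor dynamic displays — the motivating case is real-time
well-log surveillance during drilling, on the rig or in a remote operations
centre — must notice anomalies in scrolling indicator tracks.  Where they
look, for how long, and how their pupils respond are measurable proxies for
that situational awareness.  `gazesa` is an R package for analysts of such
screen-mounted eye-tracking recordings: it turns raw gaze sample streams
into fixation events and area-of-interest (AOI) attention metrics, compares
experts against novices with rank-based statistics, preprocesses
pupillograms, and implements an alerting framework that flags a subject
whose ocular activity falls below an expert baseline.

## What it computes

* **I-VT fixation detection** — gaze speed per sample (px/ms); maximal
  runs of samples with speed strictly below a threshold (default
  0.42 px/ms) become fixations, with a 60 ms minimum duration and 75 ms
  gap bridging.
* **AOI percent metrics** — the display is partitioned into named
  rectangles plus a complement region ("AOI I" = full display less the
  named AOIs).  For any window, each region's *percent fixation duration*
  and *percent fixation count*:

  pct_duration_r = 100 · (fixation time in r) / (total fixation time),

  with duration prorated by window overlap and counts attributed by onset.
  A critical-interval report defaults to the 120–170 s anomaly window.
* **Pupillogram preprocessing** — per-eye linear gap interpolation (slope
  from the 10 valid points on each side of a gap, anchored at the last
  pre-gap point), Savitzky–Golay smoothing (window 21, order 3),
  binocular averaging, baseline subtraction (change in pupil diameter,
  mm) and normalization.
* **Group statistics** — tie-corrected Kruskal–Wallis
  H = [12/(N(N+1)) Σ nᵢ(r̄ᵢ − (N+1)/2)²] / (1 − Σ(t³−t)/(N³−N)) across
  AOIs, and Dunn pairwise post hoc with
  se = √[(N(N+1)/12 − Σ(t³−t)/(12(N−1))) (1/nᵢ + 1/nⱼ)] and Bonferroni
  adjustment; expert-vs-novice z-location summaries.
* **Alerting** — sliding-window comparison of a subject against an expert
  baseline: track-loss, attention-deviation (k·σ below baseline,
  one-sided) and pupil-constriction alerts, rate-limited to 1 per 10
  minutes.
* **Synthetic data** — a generator for the five-minute, 300 Hz monitoring
  scenario (23 novices + 1 expert, anomaly at 120–170 s, blinks,
  expert/novice attention profiles) with ground truth, so the whole
  pipeline is testable without recorded data.

## Worked example

```r
library(gazesa)

scenario <- default_scenario(seed = 1)    # 300 s at 300 Hz, AOIs II/III + complement
profiles <- default_profiles()

sim <- simulate_recording(profiles$expert, scenario, seed = 42)
fix <- detect_fixations_ivt(sim$recording, threshold_px_per_ms = 0.42)
nrow(fix)
#> [1] 852

report <- critical_window_report(fix, scenario$scheme)   # anomaly window 120-170 s
report[, c("aoi", "fixation_count", "pct_duration", "pct_count")]
#>       aoi fixation_count pct_duration pct_count
#> 1   AOI I             18        14.62     13.43
#> 2  AOI II             21        14.67     15.67
#> 3 AOI III             95        70.71     70.90
```

During the anomaly the simulated expert concentrates ~70% of fixation time
on AOI III (the confirming indicators), matching the generating profile.
Comparing percent durations across AOIs for a small novice cohort:

```r
rows <- do.call(rbind, lapply(1:6, function(i) {
  s <- simulate_recording(profiles$novice, scenario, seed = 100 + i)
  percent_metrics(detect_fixations_ivt(s$recording), scenario$scheme,
                  participant_id = sprintf("novice_%02d", i))
}))
g <- split(rows$pct_duration, rows$aoi)
kruskal_wallis(g)
#> Kruskal-Wallis: H(2, 18) = 14.363, p = 0.0007607
dunn_pairwise(g)
#>   group_a group_b             pair rank_diff    se      z         p     p_adj
#> 1 AOI III  AOI II AOI III - AOI II    -5.333 3.082 -1.730 0.0835656 0.2506969
#> 2 AOI III   AOI I  AOI III - AOI I   -11.667 3.082 -3.785 0.0001536 0.0004608
#> 3  AOI II   AOI I   AOI II - AOI I    -6.333 3.082 -2.055 0.0398979 0.1196936
```

The novices' fixation time differs strongly across the AOI partition
(they dwell on the large complement region); the Dunn rows standardize
each mean-rank difference by the shared balanced-design standard error.
`monitor()` closes the loop: built on an expert baseline
(`build_baseline()` over `phase_metrics()`), it raises an
attention-deviation alert when, e.g., a novice's anomaly-window AOI III
share drops more than 2 dispersions below the expert's.

A command-line dispatcher over the same functions is included at
`inst/cli/gazesa.R` (`simulate`, `detect-fixations`, `metrics`, `pupil`,
`compare`, `monitor`).

## Documentation

The methods vignette (`vignettes/gazesa-methods.Rmd`) documents the
models, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the package's design
decisions and limitations.
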