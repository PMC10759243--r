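---
title: "Methods: gaze metrics, pupillometry and expert-baseline alerting in gazesa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze metrics, pupillometry and expert-baseline alerting in gazesa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazesa analyses screen-mounted eye-tracking recordings of operators
monitoring a dynamic display — the motivating setting is real-time well-log
surveillance, where a driller or a remote operations-centre analyst must
notice an anomaly (a kick) in scrolling indicator tracks.  The package turns
raw gaze samples into attention metrics, compares groups of participants,
and implements an alerting framework that flags a subject whose ocular
activity falls below an expert baseline.  This vignette records the models,
the parameter choices, and the design decisions behind each stage.

## Fixation detection (I-VT)

Gaze samples are classified by velocity: the speed at sample $i$ is the
Euclidean distance from the previous valid sample divided by the elapsed
time (px/ms), and a sample is a *fixation sample* when its speed is
**strictly below** the threshold $v_T$.  Maximal runs of fixation samples
become fixations; a run's duration is offset minus onset and its centroid
is the mean position of its member samples.

* `threshold_px_per_ms = 0.42` — the package keeps the threshold in pixels
  per millisecond, the scale in which screen trackers report it for this
  class of experiment; no conversion to degrees of visual angle is
  attempted because viewing geometry is not part of the data model.
* Boundary convention: a sample moving at exactly $v_T$ is a saccade
  sample.  The choice is arbitrary (a measure-zero event for continuous
  data) but fixed and tested, so the classifier is deterministic.
* `min_fix_ms = 60` — candidate runs shorter than 60 ms are discarded.
  This is standard practice for screen-based work: shorter dwells do not
  permit useful information uptake and are usually glissades or noise.
* `max_gap_ms = 75` — gaps (blinks, dropped frames) up to 75 ms are
  bridged when the speed implied across the gap stays below $v_T$; longer
  gaps always break fixations.  75 ms is below typical blink durations, so
  real blinks split fixations while single dropped frames do not.
* No post-hoc merging of adjacent fixations is performed beyond gap
  bridging.  This keeps the classifier equivalent to a one-pass run-length
  scan, which is exactly how the test suite's brute-force oracle checks it
  (randomised streams up to $10^4$ samples).

Useful consequences that the tests exercise as properties: raising the
threshold never decreases total fixation time; with `min_fix_ms = 0` the
fixation, saccade and gap times partition the valid recording span.

## AOI metrics

An AOI scheme is a set of named, pairwise-disjoint, half-open rectangles
$[x_0, x_1) \times [y_0, y_1)$ plus an implicit *complement* region
(default name "AOI I"): the whole display minus the named AOIs.  A fixation
belongs to the region containing its **centroid**; a per-sample majority
rule was considered and rejected because the centroid rule is simpler,
deterministic, and identical for the clean fixations the classifier emits.

For a window $[a, b)$ and the partition of regions,

$$\mathrm{pct\_duration}_r = 100 \cdot
  \frac{\sum_{f \in r} |[\mathrm{on}_f, \mathrm{off}_f) \cap [a,b)|}
       {\sum_{f} |[\mathrm{on}_f, \mathrm{off}_f) \cap [a,b)|},
\qquad
\mathrm{pct\_count}_r = 100 \cdot
  \frac{\#\{f \in r : \mathrm{on}_f \in [a,b)\}}
       {\#\{f : \mathrm{on}_f \in [a,b)\}}.$$

Denominators are window totals over *all* regions (the display treated as
one more AOI), so each percent column sums to 100 whenever the window holds
a fixation — the partition-conservation property the tests assert on every
simulated recording.  Edge handling at window boundaries is deliberately
asymmetric: duration is prorated by overlap (conservative, no double
counting), while a fixation is counted where its onset lies (unambiguous
integer attribution).  Windows without fixations report `NA` percents and
are flagged, never silently zeroed, so empty windows cannot bias group
statistics.  The critical-interval report defaults to the scenario's
anomaly window, 120–170 s.

## Pupillogram preprocessing

The pupil chain is: per-eye gap interpolation → per-eye Savitzky–Golay
smoothing → binocular averaging → baseline adjustment → normalization.

* **Gap interpolation.** Each interior gap no longer than `max_gap_ms`
  (default 500 ms — covers blinks, not sustained track loss) is filled
  with a straight line.  The slope is the least-squares slope through the
  10 valid points before and 10 after the gap; the line is anchored at the
  last pre-gap point, so the anchor plus the 20 flanking points form a
  21-point neighbourhood.  Anchoring at the observed pre-gap point (rather
  than the fitted line value) keeps the filled segment continuous with the
  measured data; the rule recovers affine signals exactly, which the tests
  require to $10^{-9}$ mm.  Gaps at the trace extremes, oversized gaps,
  and gaps with fewer than 10 valid points on a side stay missing.
* **Smoothing.** Savitzky–Golay with window 21 samples and polynomial
  order 3.  The window echoes the interpolation neighbourhood (70 ms at
  300 Hz — short enough to preserve dilation onsets) and order 3 is the
  conventional choice that preserves peaks; both are exposed parameters.
  Interior points use the closed-form convolution (checked against the
  $(-3,12,17,12,-3)/35$ kernel for window 5/order 2); window edges and
  segments shorter than the window fall back to a least-squares polynomial
  on the truncated window, so polynomials up to the order are reproduced
  exactly everywhere.  Missing spans propagate: smoothing never
  manufactures data, and interpolation never alters measured points.
  Interpolation runs **before** smoothing because local polynomial
  smoothing across unfilled gaps is ill-defined; the filled points are
  masked `interpolated` so provenance survives the pipeline.
* **Binocular averaging.** The two eyes carry one pupillary signal plus
  eye-specific measurement noise, so the pointwise mean (falling back to
  the single present eye) roughly halves the noise variance — the
  simulator makes this literal by construction, and a test verifies the
  factor of about one half.
* **Baseline and normalization.** The baseline $b$ is the mean valid
  diameter in a window, by default the first 5 s of the recording, before
  any scenario event.  The baselined series $d - b$ is the *change in
  pupil diameter* in mm — the scale on which dilation responses are
  compared — and $(d - b)/b$ is reported alongside as a dimensionless
  change for cross-participant comparison.  Only the subtractive stage is
  required downstream; the ratio is provided because baseline diameters
  differ between individuals.

## Group statistics

Percent metrics are compared across AOIs with the tie-corrected
Kruskal–Wallis test,

$$H = \frac{12}{N(N+1)} \sum_i n_i \left(\bar r_i - \frac{N+1}{2}\right)^2
  \Big/ \left(1 - \frac{\sum_v (t_v^3 - t_v)}{N^3 - N}\right),$$

with midranks for ties and an upper-tail $\chi^2_{k-1}$ p-value.  The
implementation is checked to $10^{-12}$ against `stats::kruskal.test` and,
at tiny $N$, against exhaustive permutation enumeration (where the
$\chi^2$ tail is only expected to agree to the accuracy of that
approximation, about a quarter at $N \le 8$).

Pairwise follow-up uses Dunn's test on the pooled ranking: for groups $i,
j$, the mean-rank difference $\bar r_i - \bar r_j$ is standardized by

$$\mathrm{se} = \sqrt{\left(\frac{N(N+1)}{12} -
  \frac{\sum_v (t_v^3 - t_v)}{12(N-1)}\right)
  \left(\frac{1}{n_i} + \frac{1}{n_j}\right)},$$

with a two-sided normal p and Bonferroni adjustment over the number of
pairs.  For a balanced tie-free design with three groups of 22
($N = 66$) the se is constant at 5.788 (3 dp) across pairs — the package's
primary exactly-reproducible numeric surface, recomputed by
`scripts/acceptance.R`.  Rows are ordered by ascending mean rank, the
conventional report layout in which every printed difference is negative.
Note the se lives on the mean-rank scale: it *grows* with the pooled $N$
and shrinks only when group sizes grow at fixed $N$.  Treating
per-participant AOI values as independent observations per group ignores
within-participant correlation across AOIs; the omnibus layout is kept
because it is the field's reporting convention for these metrics, but
inference should be read with that caveat.

`compare_expert_novices()` deliberately avoids a two-sample test: with one
expert there is no expert variance, so the expert is located inside the
novice distribution by $z = (e - \bar x)/s$ with the sample sd.

## Synthetic data generator

The generator exists so that every stage is testable without recorded
data, and its defaults *are* the study conditions the rest of the package
assumes: 300 s at 300 Hz on a 1920×1080 display, two named AOIs over the
right-hand indicator tracks (synthetic stand-in rectangles — real AOI
geometry is study-specific and supplied by config), an anomaly from 120 s
to 170 s, and a cohort of 23 novices plus 1 expert.

A recording is an alternating fixation/saccade event sequence: the
fixation's region is drawn from the active phase's weight map, its centre
uniformly inside the region, its duration lognormal (median 300 ms,
$\sigma = 0.4$ — right-skewed, typical of monitoring tasks); saccades are
linear constant-velocity segments of 20–60 ms (sufficient to exceed the
velocity threshold; no main-sequence model).  Within-fixation jitter is
Gaussian with sd 0.25 px per axis, chosen to satisfy the feasibility bound
jitter sd $\le v_T \Delta t/4$: the implied within-fixation speed is
Rayleigh with scale $\sqrt{2}\cdot 0.25/3.33$ px/ms, putting the threshold
at $4.0$ scales, so a within-fixation sample exceeds it with probability
$\approx 4\times10^{-4}$ (< 0.001, verified empirically).  Blinks arrive
as a Poisson process (15/min, 100–300 ms) and blank gaze validity and both
pupil channels; they *overlay* the event timeline rather than pausing it,
which mirrors real recordings (the behavioural event continues while the
lids close) and feeds the track-loss alert path.  Consequently the
partition identity for the event timeline is fixations + saccades =
duration, with blink spans tracked separately in the ground truth.

Attention profiles: both expert and novice spend the pre- and post-anomaly
phases identically (70% complement, 15% each named AOI), so every contrast
is isolated to the anomaly response.  During the anomaly the expert shifts
to 70% on AOI III (the confirming indicators) with a 0.5 mm raised-cosine
pupil dilation lagged 1 s; the novice stays on the complement (75%, 10% on
AOI III) with a damped 0.2 mm dilation.  Per-eye pupil channels are one
latent signal plus independent 0.05 mm noise.  Cohort novices get small
multiplicative perturbations (log-sd 0.1) of the weights and dynamics.
All of these constants are invented, documented stand-ins: the generator
reproduces the *direction* of expert/novice contrasts, not any published
magnitude, and none of its parameters were revisited after the test suite
was run.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: smooth pursuit of the scrolling trace,
main-sequence saccade kinematics, pupil foreshortening with gaze angle,
luminance-driven pupil changes, calibration drift, and head motion.

## Expert-baseline alerting

`build_baseline()` aggregates per-phase AOI metrics of one or more expert
recordings into means and dispersions; `monitor()` slides a window
(default 30 s, step 10 s — long enough for ~80 fixations, short enough to
catch a missed anomaly within one window length) and raises:

* `track_loss` when the valid-sample fraction drops below 0.6 — the
  eyes-closed cue: a drowsy subject's closed eyes suppress gaze and pupil
  data entirely;
* `attention_deviation` when a monitored AOI's percent metric falls more
  than `k_sigma` (default 2) dispersions below the phase baseline.
  Deviation is one-sided: excess attention to an AOI is not an error
  signal in this framing, only missing attention is;
* `pupil_constriction` when the baselined pupil level stays below
  −0.5 mm, a sustained constriction indexing low arousal.

With a single expert recording the dispersion estimate degenerates, so
dispersions are floored at 10 percentage points — a stand-in for the
between-window sampling variability of a 30-s percent estimate (binomial
reasoning at ~80 fixations/window gives ~5–6 pp for a 70% region;
doubling that guards against baseline over-confidence).  Alerts are
rate-limited to 1 per 10 minutes, the acceptability guideline for
operator-facing alarm systems, keeping the highest-severity alerts
(severity = relative exceedance of the trigger) under a greedy feasibility
scan, so an operator sees the single most diagnostic alert rather than a
cascade.  Windows must lie wholly inside one baseline phase; straddling
windows are skipped with a warning rather than mixing two regimes.
Real-time streaming is emulated by windowed batch over a file; socket
streaming is out of scope.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise each claim at the
scale it is stated: the brute-force I-VT oracle runs on 1,000 randomised
streams (most of a few hundred samples, five of $10^4$); empirical AOI
shares are averaged over 10 seeds per profile at full 300-s scale; the
directional expert/novice and alerting checks run 20 full cohorts of 24
five-minute 300 Hz recordings.  Statistics tables are printed at 3
decimals, and the writers round to that precision so written artifacts
re-read losslessly at the printed scale.  Timestamps are milliseconds from
recording start throughout; dialect configs handle device units and
sentinel missing codes at the I/O boundary, so the analysis core never
sees vendor conventions.

Known limitations: no dispersion-based (I-DT) or probabilistic fixation
classification; no smooth-pursuit handling (pursuit at sub-threshold speed
is classified as fixation); centroid-based AOI membership can misattribute
a fixation whose samples straddle an AOI edge; the Kruskal–Wallis layout
ignores within-participant correlation; and the alerting defaults
(`k_sigma`, window, floors) are operating points to be tuned per
deployment, not validated clinical thresholds.
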