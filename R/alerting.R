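#' Build an expert baseline profile
#'
#' Aggregates one or more expert recordings' per-phase AOI metrics (from
#' [phase_metrics()]) into a baseline the monitor compares subjects against:
#' per (phase, AOI) the mean and dispersion of percent fixation duration and
#' count, plus (optionally) the expected valid-sample fraction per phase.
#' With a single expert recording — or identical recordings — the dispersion
#' falls back to a configured floor, which also lower-bounds estimated
#' dispersions so that a near-degenerate baseline cannot make the monitor
#' hypersensitive.
#'
#' @param metrics_list list of per-recording [phase_metrics()] data frames
#'   (same phases and AOI scheme).
#' @param valid_fractions optional list (same length) of data frames
#'   `phase`, `valid_fraction`.
#' @param dispersion_floor_pct floor on percent-metric dispersions,
#'   percentage points; default 10 (between-window variability of a 30-s
#'   window estimate).
#' @param dispersion_floor_valid floor on the valid-fraction dispersion.
#' @param source identifier(s) of the expert recording(s).
#' @return List of class `baseline_profile` with elements `table` (per
#'   phase x AOI: means and dispersions), `valid` (per phase), `phases`,
#'   `n_recordings`, `source`.
#' @export
build_baseline <- function(metrics_list, valid_fractions = NULL,
                           dispersion_floor_pct = 10,
                           dispersion_floor_valid = 0.05,
                           source = "expert") {
  if (!is.list(metrics_list) || length(metrics_list) == 0L ||
      is.data.frame(metrics_list)) {
    metrics_list <- if (is.data.frame(metrics_list)) list(metrics_list) else
      stop("`metrics_list` must be a nonempty list of phase_metrics() tables")
  }
  all_m <- do.call(rbind, metrics_list)
  if (is.null(all_m$phase) || nrow(all_m) == 0L) {
    stop("baseline metrics declare no phases")
  }
  phases <- unique(all_m[c("phase", "phase_start_ms", "phase_end_ms")])
  rownames(phases) <- NULL

  floor_sd <- function(s, floor) {
    s[!is.finite(s) | s < floor] <- floor
    s
  }
  key <- interaction(all_m$phase, all_m$aoi, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) as.vector(tapply(v, key, function(z) z[1L]))
  tab <- data.frame(
    phase = first(all_m$phase), aoi = first(all_m$aoi),
    mean_pct_duration = agg(all_m$pct_duration, function(z) mean(z, na.rm = TRUE)),
    sd_pct_duration = floor_sd(agg(all_m$pct_duration, function(z) stats::sd(z)),
                               dispersion_floor_pct),
    mean_pct_count = agg(all_m$pct_count, function(z) mean(z, na.rm = TRUE)),
    sd_pct_count = floor_sd(agg(all_m$pct_count, function(z) stats::sd(z)),
                            dispersion_floor_pct))

  valid <- NULL
  if (!is.null(valid_fractions)) {
    vf <- do.call(rbind, valid_fractions)
    valid <- data.frame(
      phase = as.vector(tapply(vf$phase, vf$phase, function(z) z[1L])),
      mean_valid = as.numeric(tapply(vf$valid_fraction, vf$phase, mean)),
      sd_valid = floor_sd(as.numeric(tapply(vf$valid_fraction, vf$phase, stats::sd)),
                          dispersion_floor_valid))
  }
  structure(list(table = tab, valid = valid, phases = phases,
                 n_recordings = length(metrics_list), source = source),
            class = "baseline_profile")
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat(sprintf("<baseline_profile> %d phase(s) x %d AOI(s), from %d recording(s)\n",
              nrow(x$phases), length(unique(x$table$aoi)), x$n_recordings))
  print(x$table, digits = 3)
  invisible(x)
}

#' Serialize / read a baseline profile (JSON)
#'
#' @param baseline a `baseline_profile`.
#' @param path file path.
#' @export
write_baseline <- function(baseline, path) {
  jsonlite::write_json(unclass(baseline), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$table <- as.data.frame(x$table)
  x$phases <- as.data.frame(x$phases)
  if (!is.null(x$valid)) x$valid <- as.data.frame(x$valid)
  structure(x, class = "baseline_profile")
}

# keep at most `max_n` alerts in any sliding span of `period_ms`,
# preferring higher severity (ties: earlier window first)
rate_limit_alerts <- function(alerts, max_n, period_ms) {
  if (nrow(alerts) <= max_n) return(alerts)
  ord <- order(-alerts$severity, alerts$window_start_ms)
  kept_t <- numeric(0)
  kept <- logical(nrow(alerts))
  feasible <- function(times) {
    times <- sort(times)
    k <- length(times)
    if (k <= max_n) return(TRUE)
    all(times[seq((max_n + 1L), k)] - times[seq_len(k - max_n)] >= period_ms)
  }
  for (i in ord) {
    cand <- c(kept_t, alerts$window_start_ms[i])
    if (feasible(cand)) {
      kept_t <- cand
      kept[i] <- TRUE
    }
  }
  out <- alerts[kept, , drop = FALSE]
  out[order(out$window_start_ms), , drop = FALSE]
}

empty_alerts <- function() {
  data.frame(window_start_ms = numeric(0), window_end_ms = numeric(0),
             phase = character(0), kind = character(0), metric = character(0),
             observed = numeric(0), baseline = numeric(0),
             threshold = numeric(0), severity = numeric(0))
}

#' Monitor a recording against an expert baseline
#'
#' Emulated real-time monitoring by sliding-window batch analysis: over
#' windows of `window_s` seconds advanced by `step_s`, the monitor raises
#'
#' * `track_loss` when the window's valid-sample fraction falls below
#'   `min_valid_fraction` (the eyes-closed / tracking-lost cue: a drowsy
#'   subject's closed eyes suppress fixation and pupil data entirely);
#' * `attention_deviation` when a monitored AOI's percent metric falls more
#'   than `k_sigma` baseline dispersions *below* the expert baseline for the
#'   window's phase (one-sided: only missing attention triggers);
#' * `pupil_constriction` when the mean baselined pupil level drops below
#'   `pupil_drop_mm` (a sustained constriction indexing low arousal).
#'
#' Alerts are then rate-limited to at most `max_alert_rate` per 10 minutes
#' (the acceptability guideline for operator-facing alarm systems), keeping
#' the highest-severity alerts.  Windows not fully contained in a baseline
#' phase are skipped with a warning.
#'
#' @param recording the subject's [gaze_recording()].
#' @param scheme an [aoi_scheme()].
#' @param baseline a `baseline_profile` from [build_baseline()].
#' @param window_s,step_s sliding-window length and step, seconds.
#' @param k_sigma deviation threshold in baseline dispersions; default 2.
#' @param min_valid_fraction minimum valid-sample fraction; default 0.6.
#' @param max_alert_rate maximum alerts kept per 10-minute span; default 1.
#' @param metric monitored percent metric, `"pct_duration"` or
#'   `"pct_count"`.
#' @param pupil_drop_mm pupil-constriction threshold, mm change from the
#'   subject's own baseline; default -0.5.
#' @param threshold_px_per_ms,min_fix_ms,max_gap_ms fixation-detection
#'   parameters (see [detect_fixations_ivt()]).
#' @return Data frame of class `alert_table` (one row per kept alert, time
#'   ordered): window bounds, `phase`, `kind`, `metric`, `observed`,
#'   `baseline`, `threshold`, `severity` (relative exceedance of the
#'   trigger).  The unlimited alert list is in the `raw_alerts` attribute.
#' @export
monitor <- function(recording, scheme, baseline,
                    window_s = 30, step_s = 10, k_sigma = 2,
                    min_valid_fraction = 0.6, max_alert_rate = 1,
                    metric = c("pct_duration", "pct_count"),
                    pupil_drop_mm = -0.5,
                    threshold_px_per_ms = 0.42, min_fix_ms = 60,
                    max_gap_ms = 75) {
  metric <- match.arg(metric)
  if (!(window_s >= step_s && step_s > 0)) stop("need window_s >= step_s > 0")
  win_ms <- window_s * 1000
  step_ms <- step_s * 1000
  span <- max(recording$samples$t_ms)
  if (win_ms > span) stop("window longer than the recording")

  fixations <- detect_fixations_ivt(recording,
                                    threshold_px_per_ms = threshold_px_per_ms,
                                    min_fix_ms = min_fix_ms,
                                    max_gap_ms = max_gap_ms)
  ptrace <- tryCatch(suppressWarnings(pupillogram(recording)),
                     error = function(e) NULL)

  mcol <- paste0("mean_", metric)
  scol <- paste0("sd_", metric)
  starts <- seq(0, span - win_ms, by = step_ms)
  alerts <- list()
  n_skipped <- 0L
  for (ws in starts) {
    we <- ws + win_ms
    ph <- baseline$phases$phase[baseline$phases$phase_start_ms <= ws &
                                  baseline$phases$phase_end_ms >= we]
    if (length(ph) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    ph <- ph[1L]

    vf <- valid_fraction(recording, c(ws, we))
    if (is.na(vf) || vf < min_valid_fraction) {
      vf0 <- if (is.na(vf)) 0 else vf
      alerts[[length(alerts) + 1L]] <- data.frame(
        window_start_ms = ws, window_end_ms = we, phase = ph,
        kind = "track_loss", metric = "valid_fraction",
        observed = vf0, baseline = NA_real_, threshold = min_valid_fraction,
        severity = (min_valid_fraction - vf0) / min_valid_fraction)
      next   # too little data in window for the metric checks
    }

    m <- suppressMessages(percent_metrics(fixations, scheme, window = c(ws, we)))
    base_ph <- baseline$table[baseline$table$phase == ph, ]
    for (j in seq_len(nrow(base_ph))) {
      a <- base_ph$aoi[j]
      obs <- m[[metric]][m$aoi == a]
      if (length(obs) != 1L || !is.finite(obs)) next
      trigger <- base_ph[[mcol]][j] - k_sigma * base_ph[[scol]][j]
      if (obs < trigger) {
        zdef <- (base_ph[[mcol]][j] - obs) / base_ph[[scol]][j]
        alerts[[length(alerts) + 1L]] <- data.frame(
          window_start_ms = ws, window_end_ms = we, phase = ph,
          kind = "attention_deviation", metric = paste(a, metric),
          observed = obs, baseline = base_ph[[mcol]][j], threshold = trigger,
          severity = (zdef - k_sigma) / k_sigma)
      }
    }

    if (!is.null(ptrace)) {
      sel <- ptrace$t_ms >= ws & ptrace$t_ms < we & ptrace$mask != "missing"
      if (any(sel)) {
        lvl <- mean(ptrace$d[sel])
        if (lvl < pupil_drop_mm) {
          alerts[[length(alerts) + 1L]] <- data.frame(
            window_start_ms = ws, window_end_ms = we, phase = ph,
            kind = "pupil_constriction", metric = "pupil_change_mm",
            observed = lvl, baseline = 0, threshold = pupil_drop_mm,
            severity = (pupil_drop_mm - lvl) / abs(pupil_drop_mm))
        }
      }
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("monitor: %d window(s) skipped (no baseline phase fully covers them)",
                    n_skipped))
  }
  raw <- if (length(alerts) > 0L) do.call(rbind, alerts) else empty_alerts()
  rownames(raw) <- NULL
  out <- rate_limit_alerts(raw, max_n = max_alert_rate, period_ms = 600000)
  rownames(out) <- NULL
  attr(out, "raw_alerts") <- raw
  class(out) <- c("alert_table", "data.frame")
  out
}
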