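#' Per-sample gaze speed
#'
#' Computes gaze speed in pixels per millisecond, aligned to samples: the
#' speed at sample *i* is the Euclidean distance from the previous *valid*
#' sample divided by the elapsed time.  Speed is undefined (`NA`) at the
#' first valid sample, at invalid samples, and across gaps longer than
#' `max_gap_ms` (blinks bridge a gap only when it is short enough that the
#' implied speed is meaningful).
#'
#' @param recording a [gaze_recording()].
#' @param max_gap_ms longest inter-sample gap (ms) across which a speed is
#'   still computed; default 75 ms.
#' @return A numeric vector of class `velocity_series`, one entry per sample
#'   (`NA` where undefined), with attributes `t_ms` (sample times) and
#'   `valid` (per-sample gaze validity, either eye valid with finite x/y).
#' @examples
#' s <- data.frame(t_ms = c(0, 10), x = c(0, 3), y = c(0, 4),
#'                 pupil_l = 3, pupil_r = 3, valid_l = TRUE, valid_r = TRUE)
#' compute_velocity(gaze_recording(s))  # 5 px over 10 ms -> 0.5 px/ms
#' @export
compute_velocity <- function(recording, max_gap_ms = 75) {
  if (!is.finite(max_gap_ms) || max_gap_ms <= 0) stop("`max_gap_ms` must be positive")
  s <- recording$samples
  valid <- (s$valid_l | s$valid_r) & is.finite(s$x) & is.finite(s$y)
  if (sum(valid) < 2L) {
    stop("insufficient data: fewer than 2 valid samples in recording")
  }
  iv <- which(valid)
  dtv <- diff(s$t_ms[iv])
  sp <- sqrt(diff(s$x[iv])^2 + diff(s$y[iv])^2) / dtv
  sp[dtv > max_gap_ms] <- NA_real_
  speed <- rep(NA_real_, nrow(s))
  speed[iv[-1L]] <- sp
  structure(speed, t_ms = s$t_ms, valid = valid, max_gap_ms = max_gap_ms,
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d samples, %d with defined speed (px/ms)\n",
              length(x), sum(!is.na(x))))
  invisible(x)
}

#' I-VT fixation detection
#'
#' Classifies gaze samples into fixations with the velocity-threshold (I-VT)
#' algorithm: maximal runs of samples whose speed stays *strictly below* the
#' threshold form candidate fixations (a sample moving exactly at the
#' threshold counts as saccade); candidates shorter than `min_fix_ms` are
#' discarded.  Gaps no longer than `max_gap_ms` (short blinks, dropped
#' frames) are bridged when the speed implied across the gap stays below the
#' threshold; longer gaps break fixations.
#'
#' @param recording a [gaze_recording()].
#' @param threshold_px_per_ms velocity threshold in pixels per millisecond;
#'   default 0.42, the conventional screen-tracker setting this pipeline is
#'   built around.
#' @param min_fix_ms minimum fixation duration (ms); default 60.
#' @param max_gap_ms see [compute_velocity()]; default 75 ms.
#' @return A data frame of class `fixation_table`, one row per fixation in
#'   time order, with columns `index` (1-based time order), `onset_ms`,
#'   `offset_ms`, `duration_ms` and the member-sample centroid `cx`, `cy`.
#' @examples
#' rec <- gaze_recording(data.frame(
#'   t_ms = seq(0, 500, by = 10), x = 100, y = 100,
#'   pupil_l = 3, pupil_r = 3, valid_l = TRUE, valid_r = TRUE))
#' detect_fixations_ivt(rec)
#' @export
detect_fixations_ivt <- function(recording, threshold_px_per_ms = 0.42,
                                 min_fix_ms = 60, max_gap_ms = 75) {
  if (!is.finite(threshold_px_per_ms) || threshold_px_per_ms <= 0) {
    stop("`threshold_px_per_ms` must be positive")
  }
  if (min_fix_ms < 0) stop("`min_fix_ms` must be nonnegative")
  v <- compute_velocity(recording, max_gap_ms = max_gap_ms)
  s <- recording$samples
  iv <- which(attr(v, "valid"))
  sp <- unclass(v)[iv]                     # speed at each valid sample
  slow <- !is.na(sp) & sp < threshold_px_per_ms

  r <- rle(slow)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)

  rows <- lapply(keep, function(k) {
    # run of slow transitions at valid positions run_start..run_end; the
    # fixation also includes the sample the first slow transition came from
    first <- run_start[k] - 1L            # >= 1: the first speed is always NA
    last <- run_end[k]
    members <- iv[first:last]
    data.frame(onset_ms = s$t_ms[members[1L]],
               offset_ms = s$t_ms[members[length(members)]],
               cx = mean(s$x[members]), cy = mean(s$y[members]))
  })
  fix <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
               cx = numeric(0), cy = numeric(0))
  }
  fix$duration_ms <- fix$offset_ms - fix$onset_ms
  fix <- fix[fix$duration_ms >= min_fix_ms, , drop = FALSE]
  fix <- fix[order(fix$onset_ms), , drop = FALSE]
  fix <- data.frame(index = seq_len(nrow(fix)),
                    onset_ms = fix$onset_ms, offset_ms = fix$offset_ms,
                    duration_ms = fix$duration_ms, cx = fix$cx, cy = fix$cy)
  rownames(fix) <- NULL
  structure(fix,
            threshold_px_per_ms = threshold_px_per_ms,
            min_fix_ms = min_fix_ms, max_gap_ms = max_gap_ms,
            class = c("fixation_table", "data.frame"))
}
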