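#' Construct a pupil-diameter trace
#'
#' A `pupil_trace` is one participant's pupil-diameter time series together
#' with per-point provenance (`measured`, `interpolated`, `missing`) and a
#' processing-stage label.  Stages advance along the preprocessing chain
#' `raw -> filled -> smoothed -> averaged -> normalized`.
#'
#' @param t_ms sample times, strictly increasing milliseconds.
#' @param d pupil diameter in mm (`NA` where missing).
#' @param mask optional character vector in
#'   `c("measured", "interpolated", "missing")`; by default `measured` where
#'   `d` is finite, else `missing`.
#' @param stage processing-stage label.
#' @return Data frame of class `pupil_trace` with columns `t_ms`, `d`,
#'   `mask` and attribute `stage`.
#' @export
pupil_trace <- function(t_ms, d, mask = NULL,
                        stage = c("raw", "filled", "smoothed", "averaged",
                                  "baselined", "normalized")) {
  stage <- match.arg(stage)
  stopifnot(length(t_ms) == length(d))
  if (length(t_ms) > 1L && any(diff(t_ms) <= 0)) {
    stop("`t_ms` must be strictly increasing")
  }
  if (is.null(mask)) {
    mask <- ifelse(is.finite(d), "measured", "missing")
  }
  if (!all(mask %in% c("measured", "interpolated", "missing"))) {
    stop("mask entries must be measured / interpolated / missing")
  }
  if (any(mask == "missing" & is.finite(d))) d[mask == "missing"] <- NA_real_
  if (any(mask != "missing" & !is.finite(d))) {
    stop("non-missing points must have finite diameters")
  }
  if (stage %in% c("raw", "filled", "smoothed", "averaged") &&
      any(d[mask != "missing"] <= 0)) {
    stop("pupil diameters must be positive at mm stages")
  }
  structure(data.frame(t_ms = t_ms, d = d, mask = mask),
            stage = stage, class = c("pupil_trace", "data.frame"))
}

trace_stage <- function(trace) attr(trace, "stage")

require_stage <- function(trace, allowed, op) {
  st <- trace_stage(trace)
  if (!st %in% allowed) {
    stop(sprintf("%s expects a trace at stage %s, got \"%s\"",
                 op, paste(shQuote(allowed), collapse = " or "), st))
  }
  invisible(st)
}

#' Extract the per-eye raw pupil traces of a recording
#'
#' @param recording a [gaze_recording()].
#' @return `list(left =, right =)` of raw-stage [pupil_trace()]s on the
#'   recording's time base.
#' @export
pupil_traces <- function(recording) {
  s <- recording$samples
  list(left = pupil_trace(s$t_ms, s$pupil_l, stage = "raw"),
       right = pupil_trace(s$t_ms, s$pupil_r, stage = "raw"))
}

# index runs of missing points: list of (from, to) integer ranges
missing_runs <- function(mask) {
  r <- rle(mask == "missing")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], ends[k]))
}

#' Fill short pupil gaps by local-slope linear interpolation
#'
#' Blinks and brief track losses leave gaps in the pupillogram.  Each
#' interior gap no longer than `max_gap_ms` is filled with a straight line:
#' the slope is the least-squares slope through the `half_window` valid
#' points immediately before and the `half_window` immediately after the gap
#' (20 flanking points at the default, with the last pre-gap point serving
#' as the line's anchor — a 21-point neighbourhood), and the line passes
#' through that anchor point.  Gaps at the extremes, gaps longer than
#' `max_gap_ms`, and gaps without `half_window` valid points on both sides
#' are left missing (the latter with a warning).
#'
#' @param trace a raw-stage [pupil_trace()].
#' @param half_window number of valid points used on each side; default 10.
#' @param max_gap_ms longest fillable gap in ms; default 500 (covers blinks,
#'   not sustained track loss).
#' @return The trace at stage `"filled"`; filled points are masked
#'   `interpolated`, measured points are never altered.
#' @export
interpolate_gaps <- function(trace, half_window = 10, max_gap_ms = 500) {
  require_stage(trace, "raw", "interpolate_gaps")
  if (half_window < 1) stop("`half_window` must be >= 1")
  t <- trace$t_ms
  d <- trace$d
  mask <- trace$mask
  n_skipped <- 0L

  for (run in missing_runs(mask)) {
    i0 <- run[1L]; i1 <- run[2L]
    if (i0 == 1L || i1 == length(d)) next            # extreme gap: leave missing
    gap_ms <- t[i1 + 1L] - t[i0 - 1L]
    if (gap_ms > max_gap_ms) next
    pre <- which(mask[seq_len(i0 - 1L)] != "missing")
    post <- which(mask[seq((i1 + 1L), length(d))] != "missing") + i1
    if (length(pre) < half_window || length(post) < half_window) {
      n_skipped <- n_skipped + 1L
      next
    }
    pre <- utils::tail(pre, half_window)
    post <- utils::head(post, half_window)
    pts <- c(pre, post)
    tt <- t[pts]; dd <- d[pts]
    slope <- sum((tt - mean(tt)) * (dd - mean(dd))) / sum((tt - mean(tt))^2)
    anchor <- utils::tail(pre, 1L)                   # last valid point before gap
    fill <- seq(i0, i1)
    d[fill] <- d[anchor] + slope * (t[fill] - t[anchor])
    mask[fill] <- "interpolated"
  }
  if (n_skipped > 0L) {
    warning(sprintf(
      "interpolate_gaps: %d gap(s) left missing (fewer than %d valid points on one side)",
      n_skipped, half_window))
  }
  pupil_trace(t, d, mask, stage = "filled")
}

# least-squares polynomial smoothing of one short segment (< SG window)
fit_poly_segment <- function(t, d, polyorder) {
  k <- min(polyorder, length(d) - 1L)
  if (k < 1L) return(d)
  tc <- t - mean(t)
  stats::fitted(stats::lm(d ~ stats::poly(tc, k, raw = TRUE)))
}

#' Savitzky-Golay smoothing of a pupil trace
#'
#' Local least-squares polynomial smoothing with an odd window.  Contiguous
#' present (measured/interpolated) segments are smoothed independently;
#' missing spans propagate as missing and are never converted to data.
#' Interior points of a long segment use the standard Savitzky-Golay
#' convolution; the window ends and segments shorter than the window fall
#' back to a polynomial fit on the available (truncated) window, which
#' preserves the filter's polynomial-reproduction property at the edges.
#'
#' @param trace a gap-filled [pupil_trace()] (raw accepted when it has no
#'   gaps to fill).
#' @param window odd window length in samples; default 21.
#' @param polyorder polynomial order, less than `window`; default 3.
#' @return The trace at stage `"smoothed"`.
#' @export
smooth_sg <- function(trace, window = 21, polyorder = 3) {
  require_stage(trace, c("raw", "filled"), "smooth_sg")
  if (window %% 2 != 1) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  if (window >= nrow(trace)) {
    stop(sprintf("`window` (%d) must be smaller than the trace length (%d)",
                 window, nrow(trace)))
  }
  d <- trace$d
  present <- trace$mask != "missing"
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    seg <- seq(starts[k], ends[k])
    if (length(seg) >= window) {
      d[seg] <- signal::sgolayfilt(trace$d[seg], p = polyorder, n = window)
    } else {
      d[seg] <- fit_poly_segment(trace$t_ms[seg], trace$d[seg], polyorder)
    }
  }
  out <- trace
  out$d <- d
  attr(out, "stage") <- "smoothed"
  out
}

#' Average the two eyes' pupil traces
#'
#' Pointwise binocular mean on a shared time base: the mean where both eyes
#' are present, the single value where only one is, missing where both are.
#' Since the two eyes carry one common pupillary signal plus eye-specific
#' measurement noise, averaging roughly halves the noise variance.
#'
#' @param left,right [pupil_trace()]s at the same stage on identical time
#'   bases.
#' @return A trace at stage `"averaged"`; a point's mask is `measured` only
#'   when every contributing eye was measured.
#' @export
average_binocular <- function(left, right) {
  if (nrow(left) != nrow(right) || any(left$t_ms != right$t_ms)) {
    stop("alignment error: left and right traces must share one time base")
  }
  lp <- left$mask != "missing"
  rp <- right$mask != "missing"
  d <- ifelse(lp & rp, (left$d + right$d) / 2,
              ifelse(lp, left$d, ifelse(rp, right$d, NA_real_)))
  interp <- (lp & left$mask == "interpolated") | (rp & right$mask == "interpolated")
  mask <- ifelse(!lp & !rp, "missing", ifelse(interp, "interpolated", "measured"))
  pupil_trace(left$t_ms, d, mask, stage = "averaged")
}

#' Baseline adjustment and normalization
#'
#' Subtracts the participant's own baseline pupil diameter — the mean of the
#' valid diameters inside `baseline_window` — giving the *change in pupil
#' diameter* in mm.  A dimensionless normalized change, (d - b)/b, is
#' reported alongside for cross-participant comparison.
#'
#' @param trace an averaged (or smoothed, for monocular use)
#'   [pupil_trace()].
#' @param baseline_window `c(start_ms, end_ms)`; default the first 5 s.
#' @return The trace at stage `"normalized"`: column `d` holds the baseline-
#'   subtracted change in mm, column `d_norm` the normalized change, and
#'   attribute `baseline_mm` the baseline.  A window with no valid data is
#'   an error; less than 1 s of valid data draws a warning.
#' @export
baseline_normalize <- function(trace, baseline_window = c(0, 5000)) {
  require_stage(trace, c("smoothed", "averaged"), "baseline_normalize")
  sel <- trace$t_ms >= baseline_window[1L] & trace$t_ms < baseline_window[2L] &
    trace$mask != "missing"
  if (!any(sel)) stop("empty baseline window: no valid pupil data in it")
  dt <- stats::median(diff(trace$t_ms))
  if (sum(sel) * dt < 1000) {
    warning("baseline window holds less than 1 s of valid pupil data")
  }
  b <- mean(trace$d[sel])
  out <- trace
  out$d <- trace$d - b
  out$d_norm <- (trace$d - b) / b
  attr(out, "stage") <- "normalized"
  attr(out, "baseline_mm") <- b
  out
}

#' Full pupillogram preprocessing chain
#'
#' Composition of the preprocessing stages on a gaze recording's pupil
#' channels: per-eye gap interpolation, per-eye Savitzky-Golay smoothing,
#' binocular averaging, then baseline adjustment with normalization.  Stage
#' provenance is retained in the `stages` attribute.
#'
#' @param recording a [gaze_recording()] with pupil data on at least one
#'   eye.
#' @param half_window,max_gap_ms see [interpolate_gaps()].
#' @param sg_window,sg_order see [smooth_sg()].
#' @param baseline_window see [baseline_normalize()].
#' @return A normalized [pupil_trace()] (column `d` = change in pupil
#'   diameter, mm; `d_norm` = dimensionless change), with attributes
#'   `baseline_mm` and `stages`.
#' @export
pupillogram <- function(recording, half_window = 10, max_gap_ms = 500,
                        sg_window = 21, sg_order = 3,
                        baseline_window = c(0, 5000)) {
  tr <- pupil_traces(recording)
  if (all(tr$left$mask == "missing") && all(tr$right$mask == "missing")) {
    stop("recording has no pupil data on either eye")
  }
  process_eye <- function(x) {
    if (all(x$mask == "missing")) {
      attr(x, "stage") <- "smoothed"   # pass-through empty channel
      return(x)
    }
    smooth_sg(interpolate_gaps(x, half_window = half_window,
                               max_gap_ms = max_gap_ms),
              window = sg_window, polyorder = sg_order)
  }
  avg <- average_binocular(process_eye(tr$left), process_eye(tr$right))
  out <- baseline_normalize(avg, baseline_window = baseline_window)
  attr(out, "stages") <- c("raw", "filled", "smoothed", "averaged", "normalized")
  out
}
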