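#' Construct a gaze recording
#'
#' A `gaze_recording` bundles a time-ordered table of raw gaze samples with
#' the nominal sampling rate and the screen geometry.  It is the sole raw
#' input of the analysis pipeline: fixation detection, AOI metrics and
#' pupillometry all start from it.
#'
#' @param samples data frame with columns `t_ms` (milliseconds from recording
#'   start), `x`, `y` (gaze position in screen pixels, origin top-left, y
#'   increasing downward), `pupil_l`, `pupil_r` (pupil diameter in mm, `NA`
#'   when the eye was not measured) and logical `valid_l`, `valid_r`.
#' @param rate_hz nominal sampling rate in Hz.  If `NULL`, inferred from the
#'   median inter-sample interval.  A declared rate inconsistent with that
#'   interval by more than 10 percent is rejected.
#' @param screen integer vector `c(width, height)` of the display, pixels.
#'
#' @return An object of class `gaze_recording`: a list with elements
#'   `samples`, `rate_hz`, `screen_w`, `screen_h`.
#'
#' @details Invariants enforced: timestamps strictly increasing; `x`, `y`
#'   finite whenever either eye is valid; pupil diameters, when present, in
#'   (0, 10) mm.
#'
#' @examples
#' s <- data.frame(t_ms = c(0, 10, 20), x = 1, y = 2,
#'                 pupil_l = 3, pupil_r = 3.2,
#'                 valid_l = TRUE, valid_r = TRUE)
#' gaze_recording(s, screen = c(1920, 1080))
#' @export
gaze_recording <- function(samples, rate_hz = NULL, screen = c(1920, 1080)) {
  req <- c("t_ms", "x", "y", "pupil_l", "pupil_r", "valid_l", "valid_r")
  if (!is.data.frame(samples)) stop("`samples` must be a data frame")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0L) {
    stop("`samples` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- samples[req]
  samples$valid_l <- as.logical(samples$valid_l)
  samples$valid_r <- as.logical(samples$valid_r)
  samples$valid_l[is.na(samples$valid_l)] <- FALSE
  samples$valid_r[is.na(samples$valid_r)] <- FALSE
  rownames(samples) <- NULL

  if (nrow(samples) > 0L && any(samples$t_ms < 0)) {
    stop("timestamps must be nonnegative milliseconds from recording start")
  }
  dt <- diff(samples$t_ms)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf(
      "timestamps must be strictly increasing; first violation at row %d (t = %g follows t = %g)",
      bad, samples$t_ms[bad], samples$t_ms[bad - 1L]))
  }

  any_valid <- samples$valid_l | samples$valid_r
  if (any(any_valid & (!is.finite(samples$x) | !is.finite(samples$y)))) {
    stop("gaze x/y must be finite on samples where either eye is valid")
  }
  for (p in c("pupil_l", "pupil_r")) {
    d <- samples[[p]]
    if (any(!is.na(d) & (d <= 0 | d >= 10))) {
      stop(sprintf("%s values must lie in (0, 10) mm when present", p))
    }
  }

  if (length(screen) != 2L || any(!is.finite(screen)) || any(screen <= 0)) {
    stop("`screen` must be c(width, height) with positive entries")
  }

  if (is.null(rate_hz)) {
    if (length(dt) == 0L) stop("cannot infer sampling rate from fewer than 2 samples")
    rate_hz <- 1000 / stats::median(dt)
  } else {
    if (!is.finite(rate_hz) || rate_hz <= 0) stop("`rate_hz` must be positive")
    if (length(dt) > 0L) {
      implied <- 1000 / stats::median(dt)
      if (abs(implied - rate_hz) > 0.1 * rate_hz) {
        stop(sprintf(
          "declared rate %.6g Hz inconsistent with median inter-sample interval (implies %.6g Hz)",
          rate_hz, implied))
      }
    }
  }

  structure(
    list(samples = samples, rate_hz = rate_hz,
         screen_w = screen[1L], screen_h = screen[2L]),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  span <- if (n > 0L) diff(range(x$samples$t_ms)) else 0
  valid <- if (n > 0L) mean(x$samples$valid_l | x$samples$valid_r) else NA_real_
  cat(sprintf("<gaze_recording> %d samples, %.1f s at %.6g Hz, screen %dx%d px, %.1f%% valid\n",
              n, span / 1000, x$rate_hz, x$screen_w, x$screen_h, 100 * valid))
  invisible(x)
}

# recording span in ms (first to last timestamp)
recording_span_ms <- function(recording) {
  t <- recording$samples$t_ms
  if (length(t) < 2L) return(0)
  t[length(t)] - t[1L]
}

#' Fraction of valid samples in a time window
#'
#' A sample counts as valid when at least one eye is valid.  Used both for
#' quality reporting and for the track-loss alert path (eyes closed or
#' tracking lost suppress valid samples).
#'
#' @param recording a [gaze_recording()].
#' @param window numeric `c(start_ms, end_ms)`; default the full recording.
#' @return Fraction in \[0, 1\], or `NA` if the window holds no samples.
#' @export
valid_fraction <- function(recording, window = NULL) {
  s <- recording$samples
  if (is.null(window)) {
    sel <- rep(TRUE, nrow(s))
  } else {
    sel <- s$t_ms >= window[1L] & s$t_ms < window[2L]
  }
  if (!any(sel)) return(NA_real_)
  mean(s$valid_l[sel] | s$valid_r[sel])
}
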