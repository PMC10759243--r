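#' Assign points (fixation centroids) to AOIs
#'
#' A centroid belongs to the unique named AOI whose half-open rectangle
#' `[x0, x1) x [y0, y1)` contains it, otherwise to the complement region.
#' Points outside the screen are assigned to the complement with a warning.
#'
#' @param cx,cy centroid coordinates in screen pixels (vectors), or `cx` may
#'   be a `fixation_table`, in which case its `cx`/`cy` columns are used.
#' @param scheme an [aoi_scheme()].
#' @return Character vector of region names.
#' @export
assign_aoi <- function(cx, cy = NULL, scheme) {
  if (is.data.frame(cx)) {
    stopifnot(all(c("cx", "cy") %in% names(cx)))
    cy <- cx$cy
    cx <- cx$cx
  }
  stopifnot(length(cx) == length(cy))
  out <- rep(scheme$complement_name, length(cx))
  for (i in seq_len(nrow(scheme$aois))) {
    a <- scheme$aois[i, ]
    inside <- !is.na(cx) & !is.na(cy) &
      cx >= a$x0 & cx < a$x1 & cy >= a$y0 & cy < a$y1
    out[inside] <- a$name
  }
  off <- !is.na(cx) & !is.na(cy) &
    (cx < 0 | cx >= scheme$screen_w | cy < 0 | cy >= scheme$screen_h)
  if (any(off)) {
    warning(sprintf("%d centroid(s) outside screen bounds assigned to \"%s\"",
                    sum(off), scheme$complement_name))
  }
  out
}

#' Percent fixation duration and count per AOI
#'
#' Computes, for one analysis window, the percent fixation duration (a
#' region's share of total fixation time) and percent fixation count (its
#' share of the number of fixations) over the full AOI partition — the named
#' AOIs plus the complement region, i.e. the whole display treated as one
#' more AOI.  Percent denominators are the window totals over *all* regions,
#' so within a window the percents sum to 100.
#'
#' Window edge handling: a fixation's duration contribution is its overlap
#' with the window (prorated), while it counts toward the fixation count iff
#' its onset lies in the half-open window.
#'
#' @param fixations a `fixation_table` (see [detect_fixations_ivt()]).
#' @param scheme an [aoi_scheme()].
#' @param window `c(start_ms, end_ms)`; default spans all fixations.
#' @param participant_id optional identifier carried into the output.
#' @return Data frame with one row per region: `participant_id`, `aoi`,
#'   `window_start_ms`, `window_end_ms`, `fixation_count`,
#'   `total_duration_ms`, `pct_duration`, `pct_count`.  If the window holds
#'   no fixations the counts are 0 and the percents `NA` (flagged via the
#'   `empty` attribute and a message), never silently 0.
#' @export
percent_metrics <- function(fixations, scheme, window = NULL,
                            participant_id = NA_character_) {
  fx <- as.data.frame(fixations)
  if (is.null(window)) {
    window <- if (nrow(fx) > 0L) c(min(fx$onset_ms), max(fx$offset_ms)) else c(0, 0)
  }
  if (length(window) != 2L || window[1L] >= window[2L]) {
    if (!(nrow(fx) == 0L && window[1L] == window[2L])) {
      stop("`window` must be c(start_ms, end_ms) with start < end")
    }
  }

  regions <- region_names(scheme)
  if (nrow(fx) > 0L) {
    overlap <- pmax(0, pmin(fx$offset_ms, window[2L]) - pmax(fx$onset_ms, window[1L]))
    counted <- fx$onset_ms >= window[1L] & fx$onset_ms < window[2L]
    aoi <- factor(assign_aoi(fx$cx, fx$cy, scheme), levels = regions)
    dur <- tapply(overlap, aoi, sum, default = 0)
    cnt <- tapply(as.integer(counted), aoi, sum, default = 0L)
  } else {
    dur <- stats::setNames(rep(0, length(regions)), regions)
    cnt <- stats::setNames(rep(0L, length(regions)), regions)
  }
  tot_dur <- sum(dur)
  tot_cnt <- sum(cnt)
  empty <- tot_cnt == 0L && tot_dur == 0
  if (empty) {
    message("percent_metrics: no fixations in window [",
            window[1L], ", ", window[2L], ") ms; percents undefined")
  }
  out <- data.frame(
    participant_id = participant_id,
    aoi = regions,
    window_start_ms = window[1L], window_end_ms = window[2L],
    fixation_count = as.integer(cnt[regions]),
    total_duration_ms = as.numeric(dur[regions]),
    pct_duration = if (tot_dur > 0) 100 * as.numeric(dur[regions]) / tot_dur else NA_real_,
    pct_count = if (tot_cnt > 0) 100 * as.numeric(cnt[regions]) / tot_cnt else NA_real_)
  rownames(out) <- NULL
  attr(out, "empty") <- empty
  out
}

#' Critical-interval AOI report
#'
#' [percent_metrics()] restricted to the scenario's critical anomaly window,
#' by default 2:00-2:50 (120000-170000 ms) — the interval over which expert
#' and novice attention distributions are contrasted.
#'
#' @inheritParams percent_metrics
#' @param window the anomaly window, `c(start_ms, end_ms)`.
#' @return As [percent_metrics()]; an empty window is flagged via the
#'   `empty` attribute.
#' @export
critical_window_report <- function(fixations, scheme,
                                   window = c(120000, 170000),
                                   participant_id = NA_character_) {
  percent_metrics(fixations, scheme, window = window,
                  participant_id = participant_id)
}

#' AOI metrics per scenario phase
#'
#' Convenience wrapper: one [percent_metrics()] call per phase, row-bound
#' with `phase`, `phase_start_ms`, `phase_end_ms` columns.  Used to build
#' expert baseline profiles for alerting.
#'
#' @inheritParams percent_metrics
#' @param phases data frame with columns `phase`, `start_ms`, `end_ms`.
#' @export
phase_metrics <- function(fixations, scheme, phases,
                          participant_id = NA_character_) {
  stopifnot(all(c("phase", "start_ms", "end_ms") %in% names(phases)))
  out <- do.call(rbind, lapply(seq_len(nrow(phases)), function(i) {
    m <- percent_metrics(fixations, scheme,
                         window = c(phases$start_ms[i], phases$end_ms[i]),
                         participant_id = participant_id)
    cbind(phase = phases$phase[i],
          phase_start_ms = phases$start_ms[i],
          phase_end_ms = phases$end_ms[i], m)
  }))
  rownames(out) <- NULL
  out
}

#' Build a scanpath
#'
#' The scanpath is the time-ordered sequence of fixations (nodes, each
#' carrying its AOI assignment) connected by saccade segments; each
#' transition's saccade duration is the time from one fixation's offset to
#' the next one's onset.
#'
#' @param fixations a time-ordered `fixation_table`.
#' @param scheme an [aoi_scheme()].
#' @return A list of class `scanpath` with elements `nodes` (data frame
#'   `index`, `cx`, `cy`, `onset_ms`, `offset_ms`, `duration_ms`, `aoi`) and
#'   `saccades` (data frame `from`, `to`, `duration_ms`; `n - 1` rows for
#'   `n` fixations).
#' @export
build_scanpath <- function(fixations, scheme) {
  fx <- as.data.frame(fixations)
  if (nrow(fx) > 1L && any(diff(fx$onset_ms) <= 0)) {
    stop("fixations must be time-ordered")
  }
  nodes <- data.frame(index = fx$index, cx = fx$cx, cy = fx$cy,
                      onset_ms = fx$onset_ms, offset_ms = fx$offset_ms,
                      duration_ms = fx$duration_ms,
                      aoi = if (nrow(fx) > 0L) assign_aoi(fx$cx, fx$cy, scheme) else character(0))
  n <- nrow(fx)
  saccades <- if (n > 1L) {
    data.frame(from = fx$index[-n], to = fx$index[-1L],
               duration_ms = fx$onset_ms[-1L] - fx$offset_ms[-n])
  } else {
    data.frame(from = integer(0), to = integer(0), duration_ms = numeric(0))
  }
  structure(list(nodes = nodes, saccades = saccades), class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> %d fixation(s), %d saccade segment(s)\n",
              nrow(x$nodes), nrow(x$saccades)))
  if (nrow(x$nodes) > 0L) {
    tab <- table(x$nodes$aoi)
    cat("  nodes per AOI:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
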