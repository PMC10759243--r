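#' Describe the on-disk dialect of a gaze table
#'
#' Screen-mounted eye trackers export raw samples as delimited tables whose
#' column names, timestamp units and missing-value codes differ by vendor.
#' A dialect maps the package's logical columns onto one such export so that
#' different tracker exports are dialects of a single format; no column
#' naming is hard-wired into the reader.
#'
#' @param sep field delimiter (default tab).
#' @param columns named character vector mapping logical names `t_ms`,
#'   `gaze_x`, `gaze_y`, `pupil_l`, `pupil_r`, `valid_l`, `valid_r` to the
#'   physical header names in the file.  `valid_l`/`valid_r` may be `NA` to
#'   infer validity from data presence.
#' @param time_unit `"ms"` or `"us"`; timestamps are converted to
#'   milliseconds from recording start by the reader.
#' @param missing_pupil_codes numeric values (device sentinels such as -1 or
#'   0) mapped to missing pupil diameters, in addition to blank fields.
#' @return A list of class `gaze_dialect`.
#' @export
gaze_dialect <- function(sep = "\t",
                         columns = c(t_ms = "t_ms",
                                     gaze_x = "gaze_x", gaze_y = "gaze_y",
                                     pupil_l = "pupil_l", pupil_r = "pupil_r",
                                     valid_l = "valid_l", valid_r = "valid_r"),
                         time_unit = c("ms", "us"),
                         missing_pupil_codes = c(-1, 0)) {
  time_unit <- match.arg(time_unit)
  req <- c("t_ms", "gaze_x", "gaze_y", "pupil_l", "pupil_r", "valid_l", "valid_r")
  if (!all(req %in% names(columns))) {
    stop("`columns` must name all of: ", paste(req, collapse = ", "))
  }
  structure(list(sep = sep, columns = columns, time_unit = time_unit,
                 missing_pupil_codes = missing_pupil_codes),
            class = "gaze_dialect")
}

parse_logical_col <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  v <- toupper(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES", "VALID")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO", "INVALID", "")] <- FALSE
  out
}

#' Read a raw gaze table
#'
#' Reads a delimited tracker export into a validated [gaze_recording()].
#' Rows whose timestamp does not parse are rejected with a reported count
#' (never silently).  Pupil fields that are blank or equal to a device
#' sentinel become missing; an eye counts as valid only when its exported
#' validity flag is true *and* its pupil value parsed.  Gaze x/y are kept
#' where either eye is valid.
#'
#' @param path path to the delimited file (header required).
#' @param dialect a [gaze_dialect()] describing the export.
#' @param screen display size `c(width, height)` in pixels.
#' @param rate_hz declared sampling rate; inferred from timestamps if `NULL`.
#' @return A [gaze_recording()].
#' @seealso [write_gaze_table()]
#' @export
read_gaze_table <- function(path, dialect = gaze_dialect(),
                            screen = c(1920, 1080), rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "",
                           quote = "\"")
  cols <- dialect$columns
  mandatory <- c("t_ms", "gaze_x", "gaze_y", "pupil_l", "pupil_r")
  for (lg in mandatory) {
    if (!cols[[lg]] %in% names(raw)) {
      stop(sprintf("gaze table format error: missing mandatory column \"%s\" (logical column %s)",
                   cols[[lg]], lg))
    }
  }

  t <- suppressWarnings(as.numeric(raw[[cols[["t_ms"]]]]))
  bad_t <- !is.finite(t)
  if (any(bad_t)) {
    message(sprintf("read_gaze_table: rejected %d row(s) with unparseable timestamps", sum(bad_t)))
    raw <- raw[!bad_t, , drop = FALSE]
    t <- t[!bad_t]
  }
  if (dialect$time_unit == "us") t <- t / 1000

  num <- function(lg) suppressWarnings(as.numeric(raw[[cols[[lg]]]]))
  x <- num("gaze_x"); y <- num("gaze_y")
  pl <- num("pupil_l"); pr <- num("pupil_r")
  pl[pl %in% dialect$missing_pupil_codes] <- NA_real_
  pr[pr %in% dialect$missing_pupil_codes] <- NA_real_

  flag <- function(lg) {
    nm <- cols[[lg]]
    if (is.na(nm)) return(rep(NA, nrow(raw)))
    if (!nm %in% names(raw)) {
      stop(sprintf("gaze table format error: missing mandatory column \"%s\" (logical column %s)",
                   nm, lg))
    }
    parse_logical_col(raw[[nm]])
  }
  vl <- flag("valid_l"); vr <- flag("valid_r")
  # declared flag (if any) AND a parsable pupil measurement
  vl <- ifelse(is.na(vl), TRUE, vl) & !is.na(pl)
  vr <- ifelse(is.na(vr), TRUE, vr) & !is.na(pr)
  # gaze position also needs finite coordinates
  vl <- vl & is.finite(x) & is.finite(y)
  vr <- vr & is.finite(x) & is.finite(y)
  x[!(vl | vr)] <- NA_real_
  y[!(vl | vr)] <- NA_real_

  samples <- data.frame(t_ms = t, x = x, y = y,
                        pupil_l = pl, pupil_r = pr,
                        valid_l = vl, valid_r = vr)
  gaze_recording(samples, rate_hz = rate_hz, screen = screen)
}

#' Write a gaze recording as a delimited table
#'
#' Inverse of [read_gaze_table()]: emits the recording under the given
#' dialect (default logical column names, tab separated, blank missing
#' fields) so that reading the file back reproduces the recording.
#'
#' @param recording a [gaze_recording()].
#' @param path output path.
#' @param dialect a [gaze_dialect()].
#' @export
write_gaze_table <- function(recording, path, dialect = gaze_dialect()) {
  s <- recording$samples
  cols <- dialect$columns
  out <- data.frame(s$t_ms, s$x, s$y, s$pupil_l, s$pupil_r,
                    as.integer(s$valid_l), as.integer(s$valid_r))
  names(out) <- cols[c("t_ms", "gaze_x", "gaze_y", "pupil_l", "pupil_r",
                       "valid_l", "valid_r")]
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AOI configuration file
#'
#' The configuration is YAML (or JSON, by file extension) with fields
#' `screen: {w, h}`, `aois: [{name, x0, y0, x1, y1}, ...]` and optionally
#' `complement_name`.  The resulting scheme is validated: rectangles must be
#' pairwise disjoint and lie within the screen.
#'
#' @param path configuration file path.
#' @param screen optional `c(width, height)` overriding (or supplying) the
#'   screen size.
#' @return An [aoi_scheme()].
#' @export
read_aoi_config <- function(path, screen = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(screen)) {
    if (is.null(cfg$screen)) stop("AOI config declares no screen and none was supplied")
    screen <- c(cfg$screen$w, cfg$screen$h)
  }
  if (is.null(cfg$aois) || length(cfg$aois) < 1L) {
    stop("AOI config must declare at least one named rectangle")
  }
  aois <- cfg$aois
  if (!is.data.frame(aois)) {
    aois <- do.call(rbind, lapply(cfg$aois, function(a) {
      data.frame(name = a$name, x0 = a$x0, y0 = a$y0, x1 = a$x1, y1 = a$y1)
    }))
  }
  complement <- if (is.null(cfg$complement_name)) "AOI I" else cfg$complement_name
  aoi_scheme(aois, screen = screen, complement_name = complement)
}

#' Write an AOI scheme as a configuration file
#'
#' @param scheme an [aoi_scheme()].
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @export
write_aoi_config <- function(scheme, path) {
  cfg <- list(
    screen = list(w = scheme$screen_w, h = scheme$screen_h),
    complement_name = scheme$complement_name,
    aois = lapply(seq_len(nrow(scheme$aois)), function(i) {
      a <- scheme$aois[i, ]
      list(name = a$name, x0 = a$x0, y0 = a$y0, x1 = a$x1, y1 = a$y1)
    }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

round_df <- function(df, digits = 3L) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], digits)
  df
}

write_delim_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write / read a fixation table
#'
#' Plain-text, tab-separated, headered; numeric fields printed at 3 decimals
#' (sufficient for millisecond times and sub-pixel centroids) so the table
#' re-reads losslessly at the printed precision.  An empty fixation list
#' produces a header-only file.
#'
#' @param fixations a fixation table from [detect_fixations_ivt()].
#' @param path file path.
#' @return `read_fixation_table()` returns the fixation data frame.
#' @export
write_fixation_table <- function(fixations, path) {
  cols <- c("index", "onset_ms", "offset_ms", "duration_ms", "cx", "cy")
  df <- as.data.frame(fixations)[, cols, drop = FALSE]
  write_delim_table(round_df(df), path)
}

#' @rdname write_fixation_table
#' @export
read_fixation_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(df) <- c("fixation_table", "data.frame")
  df
}

#' Write / read an AOI metrics table
#'
#' One row per (participant, AOI, window): fixation count, total duration and
#' the percent fixation duration / count metrics, at 3-decimal precision.
#'
#' @param rows metrics rows from [percent_metrics()] (optionally row-bound
#'   across participants or windows).
#' @param path file path.
#' @export
write_metrics_table <- function(rows, path) {
  write_delim_table(round_df(as.data.frame(rows)), path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a pairwise comparison table
#'
#' Serialises Dunn post-hoc rows in the conventional report layout with
#' columns `pair`, `test_statistic` (mean-rank difference), `std_error`,
#' `std_test_statistic`, `sig` (raw two-sided p) and `adj_sig` (Bonferroni
#' adjusted p), all statistics at 3 decimals.
#'
#' @param rows a data frame from [dunn_pairwise()].
#' @param path file path.
#' @export
write_comparison_table <- function(rows, path) {
  df <- as.data.frame(rows)
  out <- data.frame(pair = df$pair,
                    test_statistic = df$rank_diff,
                    std_error = df$se,
                    std_test_statistic = df$z,
                    sig = df$p,
                    adj_sig = df$p_adj)
  write_delim_table(round_df(out), path)
}

#' @rdname write_comparison_table
#' @export
read_comparison_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
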