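#' Construct an AOI scheme
#'
#' An AOI scheme partitions the display into named rectangular areas of
#' interest plus an implicit complement region: every screen location outside
#' the named rectangles belongs to the complement (by default "AOI I", i.e.
#' the full display less the named AOIs).
#'
#' Rectangles are half-open, `[x0, x1) x [y0, y1)`, so a point belongs to at
#' most one named AOI and a point on a shared edge is assigned
#' deterministically.
#'
#' @param aois data frame with columns `name`, `x0`, `y0`, `x1`, `y1`
#'   (screen pixels, origin top-left).
#' @param screen `c(width, height)` of the display in pixels.
#' @param complement_name name of the implicit remainder region.
#' @return An object of class `aoi_scheme`.
#' @examples
#' aoi_scheme(data.frame(name = c("AOI II", "AOI III"),
#'                       x0 = c(100, 600), y0 = c(100, 100),
#'                       x1 = c(500, 900), y1 = c(500, 500)),
#'            screen = c(1920, 1080))
#' @export
aoi_scheme <- function(aois, screen, complement_name = "AOI I") {
  req <- c("name", "x0", "y0", "x1", "y1")
  if (!is.data.frame(aois) || !all(req %in% names(aois))) {
    stop("`aois` must be a data frame with columns name, x0, y0, x1, y1")
  }
  if (nrow(aois) < 1L) stop("at least one named AOI rectangle is required")
  aois <- aois[req]
  aois$name <- as.character(aois$name)
  rownames(aois) <- NULL
  if (anyDuplicated(aois$name)) stop("AOI names must be unique")
  if (complement_name %in% aois$name) {
    stop(sprintf("complement name %s collides with a named AOI", complement_name))
  }
  if (any(aois$x0 >= aois$x1) || any(aois$y0 >= aois$y1)) {
    stop("each rectangle needs x0 < x1 and y0 < y1")
  }
  if (length(screen) != 2L || any(screen <= 0)) {
    stop("`screen` must be c(width, height) with positive entries")
  }
  out_of_bounds <- aois$x0 < 0 | aois$y0 < 0 | aois$x1 > screen[1L] | aois$y1 > screen[2L]
  if (any(out_of_bounds)) {
    stop(sprintf("rectangle %s lies outside the %gx%g screen",
                 aois$name[which(out_of_bounds)[1L]], screen[1L], screen[2L]))
  }
  if (nrow(aois) > 1L) {
    for (i in seq_len(nrow(aois) - 1L)) {
      for (j in seq((i + 1L), nrow(aois))) {
        overlap <- aois$x0[i] < aois$x1[j] && aois$x0[j] < aois$x1[i] &&
          aois$y0[i] < aois$y1[j] && aois$y0[j] < aois$y1[i]
        if (overlap) {
          stop(sprintf("AOI rectangles overlap: %s and %s",
                       aois$name[i], aois$name[j]))
        }
      }
    }
  }
  structure(
    list(aois = aois, complement_name = complement_name,
         screen_w = screen[1L], screen_h = screen[2L]),
    class = "aoi_scheme")
}

#' @export
print.aoi_scheme <- function(x, ...) {
  cat(sprintf("<aoi_scheme> %d named AOI(s) + complement \"%s\" on %dx%d px\n",
              nrow(x$aois), x$complement_name, x$screen_w, x$screen_h))
  for (i in seq_len(nrow(x$aois))) {
    a <- x$aois[i, ]
    cat(sprintf("  %-10s [%g, %g) x [%g, %g)\n", a$name, a$x0, a$x1, a$y0, a$y1))
  }
  invisible(x)
}

# region names in reporting order: complement first, then named AOIs
region_names <- function(scheme) {
  c(scheme$complement_name, scheme$aois$name)
}
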