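#' Construct a point field
#'
#' A `point_field` holds the 2-D positions of cone cell bodies over a
#' rectangular sampling window, in micrometres. It is the common currency of
#' the package: readers produce it, the tessellation and the synthetic
#' generator consume and produce it.
#'
#' Coordinates use a continuous Cartesian convention with the origin at the
#' bottom-left of the window and y increasing upward. All coordinates (and the
#' window, when supplied) are multiplied by `unit_scale`, so tables recorded
#' in pixels can be converted to micrometres at read time. Exact duplicates --
#' points closer than 1e-9 micrometres -- are degenerate input for a Voronoi
#' tessellation and are dropped with a warning.
#'
#' @param x Numeric vector of x positions, or a two-column matrix/data frame
#'   of (x, y) positions.
#' @param y Numeric vector of y positions (ignored when `x` is two-column).
#' @param window Numeric vector `c(xmin, ymin, xmax, ymax)` in the same units
#'   as the coordinates. When `NULL`, the tight bounding box of the points
#'   expanded outward to whole micrometres is used.
#' @param label Free-text condition tag (e.g. `"RP control"`).
#' @param animal_id Free-text animal or field identifier.
#' @param unit_scale Micrometres per input coordinate unit (default 1).
#' @return An object of class `point_field` with elements `x`, `y`, `window`,
#'   `label`, `animal_id`, `unit_scale` and `n`.
#' @examples
#' pf <- point_field(c(0, 1000, 0, 1000, 500), c(0, 0, 1000, 1000, 500))
#' pf$window
#' @export
point_field <- function(x, y = NULL, window = NULL, label = "",
                        animal_id = "", unit_scale = 1) {
  if (is.null(y)) {
    m <- as.matrix(as.data.frame(x)[, 1:2])
    x <- as.numeric(m[, 1])
    y <- as.numeric(m[, 2])
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("a point field needs at least one point")
  if (anyNA(x) || anyNA(y)) stop("coordinates must not contain missing values")
  if (!is.numeric(unit_scale) || length(unit_scale) != 1L || unit_scale <= 0)
    stop("unit_scale must be a single positive number")

  x <- x * unit_scale
  y <- y * unit_scale
  if (!is.null(window)) {
    window <- as.numeric(window) * unit_scale
    if (length(window) != 4L) stop("window must be c(xmin, ymin, xmax, ymax)")
  } else {
    window <- c(floor(min(x)), floor(min(y)), ceiling(max(x)), ceiling(max(y)))
  }
  names(window) <- c("xmin", "ymin", "xmax", "ymax")
  if (window["xmax"] <= window["xmin"] || window["ymax"] <= window["ymin"])
    stop("window must have strictly positive width and height")

  # duplicate policy: coincident to within 1e-9 um -> keep first occurrence
  key <- paste(round(x * 1e9), round(y * 1e9))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate point(s) (coincident within 1e-9 um)",
                    sum(dup)))
    x <- x[!dup]
    y <- y[!dup]
  }

  out <- x < window["xmin"] | x > window["xmax"] |
         y < window["ymin"] | y > window["ymax"]
  if (any(out))
    stop(sprintf("%d point(s) lie outside the window (first at row %d)",
                 sum(out), which(out)[1]))

  structure(
    list(x = x, y = y, window = window, label = as.character(label),
         animal_id = as.character(animal_id), unit_scale = unit_scale,
         n = length(x)),
    class = "point_field"
  )
}

#' @export
print.point_field <- function(x, ...) {
  w <- x$window
  cat(sprintf("point_field: %d points in [%g, %g] x [%g, %g] um\n",
              x$n, w["xmin"], w["xmax"], w["ymin"], w["ymax"]))
  if (nzchar(x$label)) cat("  label:    ", x$label, "\n")
  if (nzchar(x$animal_id)) cat("  animal_id:", x$animal_id, "\n")
  cat(sprintf("  density:   %.1f cells/mm^2\n", cone_density(x)))
  invisible(x)
}

#' @export
as.data.frame.point_field <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}

#' Area of a point field's window
#'
#' @param field A [point_field()].
#' @param unit `"um2"` or `"mm2"`.
#' @return Window area.
#' @keywords internal
window_area <- function(field, unit = c("um2", "mm2")) {
  unit <- match.arg(unit)
  w <- field$window
  a <- (w[["xmax"]] - w[["xmin"]]) * (w[["ymax"]] - w[["ymin"]])
  if (unit == "mm2") a / 1e6 else a
}
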