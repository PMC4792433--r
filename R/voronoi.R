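#' Voronoi tessellation of a point field, clipped to the window
#'
#' Computes the Voronoi (Dirichlet) domain of every cell, clips unbounded
#' domains to the sampling window, and records each domain's area, its
#' Voronoi neighbours (domains sharing a polygon edge of positive length) and
#' whether the cell is retained as "interior" under the chosen edge rule.
#' The clipped domains partition the window, so the areas sum to the window
#' area; this invariant is checked on every call.
#'
#' Edge rules (boundary exclusion): statistics computed from clipped domains
#' are biased for cells near the window border, so those cells are flagged
#' and excluded from the area distribution, g1 and CC.
#' * `window_touch` (default): a cell is excluded iff its clipped polygon
#'   touches the window boundary (equivalently, iff its unclipped domain is
#'   unbounded or extends beyond the window).
#' * `hull_peel`: cells on the convex hull of the point set are excluded.
#'
#' The tessellation itself is delegated to [deldir::deldir()]; this package
#' adds the clipping window handling, the adjacency/interior bookkeeping and
#' the mosaic statistics built on top.
#'
#' @param field A [point_field()] with at least 2 points, not all collinear
#'   (3 or more collinear points give a degenerate tessellation and raise an
#'   error).
#' @param edge_rule `"window_touch"` or `"hull_peel"`.
#' @return An object of class `voronoi_result`: a list with `areas` (um^2,
#'   aligned with the input point order), `neighbors` (list of integer
#'   vectors), `interior` and `boundary_touch` (logical vectors), `window`,
#'   `edge_rule` and `n`.
#' @examples
#' pf <- point_field(c(250, 750), c(500, 500), window = c(0, 0, 1000, 1000))
#' compute_voronoi(pf)$areas
#' @export
compute_voronoi <- function(field, edge_rule = c("window_touch", "hull_peel")) {
  stopifnot(inherits(field, "point_field"))
  edge_rule <- match.arg(edge_rule)
  n <- field$n
  if (n < 2L) stop("insufficient points: Voronoi tessellation needs >= 2 points")
  if (n >= 3L && all_collinear(field$x, field$y))
    stop("degenerate geometry: all points are collinear")
  w <- field$window

  d <- deldir::deldir(field$x, field$y,
                      rw = c(w[["xmin"]], w[["xmax"]], w[["ymin"]], w[["ymax"]]),
                      round = FALSE, suppressMsge = TRUE)
  areas <- d$summary$dir.area

  target <- window_area(field, "um2")
  if (abs(sum(areas) - target) > 1e-6 * target)
    warning("clipped Voronoi areas do not partition the window (relative error ",
            format(abs(sum(areas) - target) / target), ")")

  dsg <- d$dirsgs
  seg_len <- sqrt((dsg$x1 - dsg$x2)^2 + (dsg$y1 - dsg$y2)^2)
  keep <- seg_len > 1e-9
  neighbors <- rep(list(integer(0)), n)
  pairs <- split(c(dsg$ind2[keep], dsg$ind1[keep]),
                 c(dsg$ind1[keep], dsg$ind2[keep]))
  neighbors[as.integer(names(pairs))] <-
    lapply(pairs, function(v) sort(unique(as.integer(v))))

  # a clipped polygon touches the window boundary iff one of its Voronoi
  # edges has an endpoint on the boundary (bp flag from the clipping step)
  on_boundary <- dsg$bp1 | dsg$bp2
  boundary_touch <- rep(FALSE, n)
  boundary_touch[unique(c(dsg$ind1[on_boundary], dsg$ind2[on_boundary]))] <- TRUE
  if (n == 2L) boundary_touch[] <- TRUE  # both half-window cells touch it

  vr <- structure(
    list(areas = areas, neighbors = neighbors, boundary_touch = boundary_touch,
         interior = NULL, window = w, edge_rule = edge_rule, n = n),
    class = "voronoi_result"
  )
  vr$interior <- interior_mask(vr, field, rule = edge_rule)
  vr
}

#' Interior-cell mask under a boundary-exclusion rule
#'
#' @param vr A [compute_voronoi()] result for `field`.
#' @param field The [point_field()] the tessellation was computed on.
#' @param rule `"window_touch"` (drop cells whose clipped polygon meets the
#'   window border) or `"hull_peel"` (drop cells on the convex hull of the
#'   point set).
#' @return Logical vector, `TRUE` for cells retained for statistics.
#' @export
interior_mask <- function(vr, field, rule = c("window_touch", "hull_peel")) {
  rule <- match.arg(rule)
  stopifnot(inherits(vr, "voronoi_result"), inherits(field, "point_field"))
  if (vr$n != field$n) stop("voronoi_result does not match field")
  if (rule == "window_touch") {
    !vr$boundary_touch
  } else {
    hull <- grDevices::chull(field$x, field$y)
    mask <- rep(TRUE, field$n)
    mask[hull] <- FALSE
    mask
  }
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat(sprintf("voronoi_result: %d cells, %d interior (%s rule)\n",
              x$n, sum(x$interior), x$edge_rule))
  cat(sprintf("  area range: %.1f - %.1f um^2\n", min(x$areas), max(x$areas)))
  invisible(x)
}

all_collinear <- function(x, y, tol = 1e-9) {
  dx <- x - x[1]
  dy <- y - y[1]
  scale <- max(abs(dx), abs(dy), 1)
  all(abs(dx * dy[2] - dy * dx[2]) < tol * scale^2) ||
    all(abs(dx) < tol) || all(abs(dy) < tol)
}
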