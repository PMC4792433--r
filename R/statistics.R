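#' g1 skewness (moment coefficient, 1/n convention)
#'
#' The skewness of a sample, computed with biased central moments in both the
#' numerator and the denominator:
#' \deqn{g_1 = \frac{\tfrac1n \sum_i (x_i - \bar x)^3}
#'                  {\left(\tfrac1n \sum_i (x_i - \bar x)^2\right)^{3/2}}}
#' Applied to interior Voronoi-domain areas, a strongly positive g1 flags the
#' long right tail produced by the cell-free centres of cone rings.
#'
#' @param values Numeric vector, length >= 3, not all equal.
#' @return The dimensionless g1 skewness.
#' @examples
#' skewness_g1(c(1, 2, 3))   # 0
#' skewness_g1(c(1, 1, 4))   # 2 / 2^1.5
#' @export
skewness_g1 <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  if (n < 3L) stop("g1 skewness needs at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("zero variance: g1 skewness is undefined")
  mean((values - m)^3) / m2^1.5
}

#' Cone density of a field
#'
#' The number of cells divided by the window area. All cells in the field are
#' counted; the boundary exclusion used for the Voronoi statistics does not
#' apply to density.
#'
#' @param field A [point_field()].
#' @return Density in cells/mm^2.
#' @export
cone_density <- function(field) {
  stopifnot(inherits(field, "point_field"))
  field$n / window_area(field, "mm2")
}

#' Coefficient of clustering (CC)
#'
#' The ratio of the global coefficient of variation of Voronoi-domain areas
#' to the mean local coefficient of variation:
#' \deqn{CC = \frac{\sigma_x / \bar x}
#'                 {\tfrac1n \sum_i \sigma_{a_i} / \bar a_i}}
#' where \eqn{x} ranges over the areas of interior cells and, for each
#' interior cell \eqn{i}, \eqn{\bar a_i} and \eqn{\sigma_{a_i}} are the mean
#' and standard deviation of the areas of its Voronoi neighbours (the focal
#' domain itself is not part of its neighbourhood).
#'
#' CC is close to 1 for a stationary random mosaic -- the global and typical
#' local variation coincide -- and rises when small and large domains
#' segregate spatially, as they do when cones cluster on rings: rim
#' neighbourhoods are uniformly small, hole-facing neighbourhoods uniformly
#' large, so local variation stays low while global variation explodes.
#' (Small neighbourhoods make the local CV a slightly biased estimate, so
#' even an ideal Poisson mosaic sits a little above 1; see the methods
#' vignette.)
#'
#' @param vr A [compute_voronoi()] result; its `interior` mask defines which
#'   cells enter the statistic.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (1/n) for both the global and local standard deviations.
#' @param cc_neighbors `"all"` (default): the neighbourhoods of interior
#'   cells may include boundary-flagged cells (with clipped areas);
#'   `"interior_only"`: boundary cells are removed from neighbourhoods.
#' @return The dimensionless CC (> 0).
#' @export
coefficient_of_clustering <- function(vr,
                                      sd_convention = c("sample", "population"),
                                      cc_neighbors = c("all", "interior_only")) {
  stopifnot(inherits(vr, "voronoi_result"))
  sd_convention <- match.arg(sd_convention)
  cc_neighbors <- match.arg(cc_neighbors)
  sdf <- if (sd_convention == "sample") stats::sd
         else function(v) sqrt(mean((v - mean(v))^2))

  interior <- which(vr$interior)
  if (length(interior) < 2L)
    stop("insufficient interior cells: CC needs at least 2")
  if (length(interior) < 10L)
    warning("fewer than 10 interior cells; CC will be unstable")

  gx <- vr$areas[interior]
  gsd <- sdf(gx)
  # relative floor absorbs tessellation round-off on exactly regular mosaics
  if (gsd <= 1e-12 * mean(gx))
    stop("zero variance: all interior Voronoi areas are equal")
  global_cv <- gsd / mean(gx)

  local_cv <- vapply(interior, function(i) {
    nb <- vr$neighbors[[i]]
    if (cc_neighbors == "interior_only") nb <- nb[vr$interior[nb]]
    if (length(nb) < 2L) return(NA_real_)
    a <- vr$areas[nb]
    if (mean(a) <= 0) return(NA_real_)
    sdf(a) / mean(a)
  }, numeric(1))
  dropped <- sum(is.na(local_cv))
  if (dropped == length(local_cv))
    stop("CC undefined: every local neighbourhood was dropped")
  if (dropped > 0L)
    warning(sprintf("%d cell(s) dropped from the local average (< 2 eligible neighbours)",
                    dropped))
  global_cv / mean(local_cv, na.rm = TRUE)
}

#' Full Voronoi-domain analysis of one field
#'
#' Runs the whole per-field pipeline: tessellation clipped to the window,
#' boundary exclusion, cell density, the interior domain-area vector (the
#' histogram input), g1 skewness and the coefficient of clustering.
#'
#' @param field A [point_field()].
#' @inheritParams compute_voronoi
#' @inheritParams coefficient_of_clustering
#' @return An object of class `mosaic_statistics`: `n_total`, `n_interior`,
#'   `density` (cells/mm^2), `areas_interior` (um^2), `skewness_g1`, `cc`,
#'   plus the field metadata and options used.
#' @examples
#' f <- generate_mosaic(synthetic_config("homogeneous", target_density = 400,
#'                                       seed = 1))
#' analyze_field(f)
#' @export
analyze_field <- function(field, edge_rule = c("window_touch", "hull_peel"),
                          sd_convention = c("sample", "population"),
                          cc_neighbors = c("all", "interior_only")) {
  edge_rule <- match.arg(edge_rule)
  sd_convention <- match.arg(sd_convention)
  cc_neighbors <- match.arg(cc_neighbors)
  vr <- compute_voronoi(field, edge_rule = edge_rule)
  areas_int <- vr$areas[vr$interior]
  if (length(areas_int) < 3L)
    stop("insufficient interior cells for mosaic statistics")
  structure(
    list(n_total = field$n,
         n_interior = length(areas_int),
         density = cone_density(field),
         areas_interior = areas_int,
         skewness_g1 = skewness_g1(areas_int),
         cc = coefficient_of_clustering(vr, sd_convention = sd_convention,
                                        cc_neighbors = cc_neighbors),
         label = field$label, animal_id = field$animal_id,
         edge_rule = edge_rule, sd_convention = sd_convention,
         cc_neighbors = cc_neighbors),
    class = "mosaic_statistics"
  )
}

#' @export
print.mosaic_statistics <- function(x, ...) {
  cat("mosaic_statistics",
      if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  cells:     %d total, %d interior (%s)\n",
              x$n_total, x$n_interior, x$edge_rule))
  cat(sprintf("  density:   %.1f cells/mm^2\n", x$density))
  cat(sprintf("  g1 skew:   %.3f\n", x$skewness_g1))
  cat(sprintf("  CC:        %.3f (%s SD, neighbours: %s)\n",
              x$cc, x$sd_convention, x$cc_neighbors))
  invisible(x)
}

#' @export
as.data.frame.mosaic_statistics <- function(x, ...) {
  data.frame(label = x$label, animal_id = x$animal_id, n_total = x$n_total,
             n_interior = x$n_interior, density = x$density,
             skewness_g1 = x$skewness_g1, cc = x$cc,
             stringsAsFactors = FALSE)
}

#' Histogram of Voronoi-domain areas
#'
#' Bins a vector of domain areas into fixed-width bins starting at 0, the
#' form in which ring and homogeneous mosaics are usually compared (ring
#' mosaics carry a long right tail).
#'
#' @param areas Numeric vector of areas (um^2), e.g. `areas_interior` from
#'   [analyze_field()].
#' @param bin_width Positive bin width in um^2.
#' @return A data frame with `bin_start`, `bin_end` and `count`; the counts
#'   sum to `length(areas)`.
#' @export
area_histogram <- function(areas, bin_width) {
  areas <- as.numeric(areas)
  if (length(areas) == 0L) stop("no areas to bin")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number")
  bin <- pmax(ceiling(areas / bin_width), 1L)  # area == 0 goes in bin 1
  counts <- tabulate(bin)
  data.frame(bin_start = (seq_along(counts) - 1) * bin_width,
             bin_end = seq_along(counts) * bin_width,
             count = counts)
}
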