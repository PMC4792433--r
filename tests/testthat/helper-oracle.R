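# Brute-force rasterized nearest-point oracle, independent of the deldir
# path: every pixel centre of a fine grid is assigned to its nearest point;
# areas are pixel counts, adjacency is 4-neighbour contact between labels,
# boundary cells are the labels seen on the raster border. 0.5 um resolution
# resolves thin boundary slivers that a 1 um raster can miss.
oracle_voronoi <- function(field, res = 0.5) {
  w <- field$window
  gx <- seq(w[["xmin"]] + res / 2, w[["xmax"]] - res / 2, by = res)
  gy <- seq(w[["ymin"]] + res / 2, w[["ymax"]] - res / 2, by = res)
  dx2 <- outer(gx, field$x, "-")^2
  dy2 <- outer(gy, field$y, "-")^2
  lab <- matrix(0L, length(gx), length(gy))
  for (j in seq_along(gy)) {
    lab[, j] <- max.col(-(dx2 + rep(dy2[j, ], each = length(gx))),
                        ties.method = "first")
  }
  areas <- tabulate(lab, field$n) * res^2
  horiz <- cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ]))
  vert <- cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
  pairs <- rbind(horiz, vert)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                        pmax(pairs[, 1], pairs[, 2])))
  neighbors <- rep(list(integer(0)), field$n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
  }
  neighbors <- lapply(neighbors, sort)
  boundary <- rep(FALSE, field$n)
  boundary[unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))] <- TRUE
  list(areas = areas, neighbors = neighbors, boundary_touch = boundary,
       interior = !boundary)
}

# CC evaluated directly from the prose formula on any areas/adjacency pair
oracle_cc <- function(areas, neighbors, interior, sd_convention = "sample") {
  sdf <- if (sd_convention == "sample") stats::sd
         else function(v) sqrt(mean((v - mean(v))^2))
  idx <- which(interior)
  global_cv <- sdf(areas[idx]) / mean(areas[idx])
  local_cv <- vapply(idx, function(i) {
    a <- areas[neighbors[[i]]]
    if (length(a) < 2) return(NA_real_)
    sdf(a) / mean(a)
  }, numeric(1))
  global_cv / mean(local_cv, na.rm = TRUE)
}

# small random fields in general position for oracle-equivalence checks
oracle_fixture_field <- function(seed, n = 12, window = c(0, 0, 1000, 1000),
                                 margin = 60) {
  set.seed(seed)
  point_field(runif(n, window[1] + margin, window[3] - margin),
              runif(n, window[2] + margin, window[4] - margin),
              window = window)
}

# force every cell interior (tiny fixtures rarely have >= 10 interior cells;
# both the package path and the oracle use the same all-cells rule)
with_all_interior <- function(vr) {
  vr$interior <- rep(TRUE, vr$n)
  vr
}
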