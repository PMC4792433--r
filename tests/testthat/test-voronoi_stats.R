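test_that("two interior points split the square through the bisector", {
  pf <- point_field(c(250, 750), c(500, 500), window = c(0, 0, 1000, 1000))
  vr <- compute_voronoi(pf)
  expect_equal(vr$areas, c(5e5, 5e5))
  expect_true(all(vr$boundary_touch))
})

test_that("3x3 grid areas match the raster oracle and the closed form", {
  pf <- point_field(c(250, 500, 750, 250, 500, 750, 250, 500, 750),
                    c(250, 250, 250, 500, 500, 500, 750, 750, 750),
                    window = c(0, 0, 1000, 1000))
  vr <- compute_voronoi(pf)
  expect_equal(vr$areas[5], 250^2)         # centre cell is the 250 um square
  orc <- oracle_voronoi(pf, res = 1)
  expect_true(all(abs(vr$areas - orc$areas) / orc$areas < 0.005))
  expect_identical(which(vr$interior), 5L)
})

test_that("clipped areas always partition the window", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(50:300, 1)
    pf <- point_field(runif(n, 0, 1000), runif(n, 0, 1000),
                      window = c(0, 0, 1000, 1000))
    vr <- compute_voronoi(pf)
    expect_lt(abs(sum(vr$areas) - 1e6) / 1e6, 1e-6)
    # adjacency is symmetric and irreflexive
    for (i in seq_len(pf$n)) {
      expect_false(i %in% vr$neighbors[[i]])
      for (j in vr$neighbors[[i]]) expect_true(i %in% vr$neighbors[[j]])
    }
    # interior cells keep at least 3 neighbours
    expect_true(all(lengths(vr$neighbors[vr$interior]) >= 3))
  }
})

test_that("window_touch interior of a 10x10 grid is the inner 8x8 block", {
  pf <- grid_field(10)
  vr <- compute_voronoi(pf)
  expect_equal(sum(vr$interior), 64)
  inner <- pf$x > 100 & pf$x < 900 & pf$y > 100 & pf$y < 900
  expect_equal(vr$interior, inner)
})

test_that("edge rules: ring of 8 around a centre point", {
  th <- 2 * pi * (0:7) / 8
  pf <- point_field(c(100 + 90 * cos(th), 100), c(100 + 90 * sin(th), 100),
                    window = c(0, 0, 200, 200))
  vr <- compute_voronoi(pf)
  expect_identical(which(vr$interior), 9L)          # only the centre survives
  hull <- interior_mask(vr, pf, rule = "hull_peel")
  expect_identical(which(hull), 9L)                 # the 8 ring points are the hull
})

test_that("degenerate geometries are rejected", {
  expect_error(compute_voronoi(point_field(1, 1, window = c(0, 0, 10, 10))),
               "insufficient points")
  expect_error(
    compute_voronoi(point_field(c(0, 100, 200, 300), c(0, 100, 200, 300))),
    "collinear")
  # all points on one circle in a big window: no interior cells
  th <- 2 * pi * (0:9) / 10
  pf <- point_field(500 + 100 * cos(th), 500 + 100 * sin(th),
                    window = c(0, 0, 1000, 1000))
  expect_error(analyze_field(pf), "insufficient interior cells")
})

test_that("g1 skewness follows the 1/n moment formula", {
  expect_equal(skewness_g1(c(1, 2, 3)), 0)
  expect_equal(skewness_g1(c(1, 1, 4)), 2 / 2^1.5)
  expect_error(skewness_g1(c(3, 3, 3)), "zero variance")
  expect_error(skewness_g1(c(1, 2)), "at least 3")
  # reflection about the mean negates g1
  for (seed in 1:10) {
    set.seed(seed)
    v <- rexp(30)
    expect_equal(skewness_g1(2 * mean(v) - v), -skewness_g1(v),
                 tolerance = 1e-12)
  }
})

test_that("CC matches the brute-force oracle on the hexagon fixture", {
  pf <- hex_field()
  vr <- with_all_interior(compute_voronoi(pf))
  orc <- oracle_voronoi(pf)
  cc_pkg <- suppressWarnings(coefficient_of_clustering(vr))
  cc_orc <- oracle_cc(orc$areas, orc$neighbors, rep(TRUE, pf$n))
  expect_lt(abs(cc_pkg - cc_orc) / cc_orc, 0.01)
})

test_that("CC degenerate cases raise the documented errors", {
  # equal areas everywhere: zero global variance
  vr <- with_all_interior(compute_voronoi(grid_field(4)))
  expect_error(suppressWarnings(coefficient_of_clustering(vr)),
               "zero variance")
  # two cells with unequal split: every neighbourhood has < 2 members
  pf <- point_field(c(200, 700), c(500, 500), window = c(0, 0, 1000, 1000))
  vr2 <- with_all_interior(compute_voronoi(pf))
  expect_error(suppressWarnings(coefficient_of_clustering(vr2)),
               "CC undefined")
})

test_that("density counts all cells over the window area", {
  set.seed(42)
  pf <- point_field(runif(100, 0, 1000), runif(100, 0, 1000),
                    window = c(0, 0, 1000, 1000))
  expect_equal(cone_density(pf), 100)
  pf2 <- point_field(pf$x / 2, pf$y / 2, window = c(0, 0, 500, 500))
  expect_equal(cone_density(pf2), 400)
})

test_that("analysis is deterministic and similarity-invariant", {
  field <- generate_mosaic(synthetic_config("ring", target_density = 1200,
                                            seed = 4))
  a <- analyze_field(field)
  b <- analyze_field(field)
  expect_identical(a, b)

  # translation
  w <- field$window
  tr <- point_field(field$x + 130, field$y - 55,
                    window = c(w[1] + 130, w[2] - 55, w[3] + 130, w[4] - 55))
  at <- analyze_field(tr)
  expect_equal(at$cc, a$cc, tolerance = 1e-9)
  expect_equal(at$skewness_g1, a$skewness_g1, tolerance = 1e-9)
  expect_equal(at$density, a$density, tolerance = 1e-12)

  # quarter-turn rotation within the window
  rot <- point_field(field$y, w[3] - field$x, window = w)
  ar <- analyze_field(rot)
  expect_equal(ar$cc, a$cc, tolerance = 1e-9)
  expect_equal(ar$skewness_g1, a$skewness_g1, tolerance = 1e-9)

  # joint scaling of points and window: dimensionless stats fixed,
  # density scales as length^-2
  s <- 2.7
  sc <- point_field(field$x * s, field$y * s, window = w * s)
  as_ <- analyze_field(sc)
  expect_equal(as_$cc, a$cc, tolerance = 1e-9)
  expect_equal(as_$skewness_g1, a$skewness_g1, tolerance = 1e-9)
  expect_equal(as_$density, a$density / s^2, tolerance = 1e-9)
})

test_that("area histogram preserves counts and flags the ring tail", {
  areas <- c(10, 20, 35, 250)
  h <- area_histogram(areas, 1000)
  expect_equal(nrow(h), 1)
  expect_equal(h$count, 4)
  h2 <- area_histogram(areas, 25)
  expect_equal(sum(h2$count), 4)
  expect_error(area_histogram(areas, 0), "positive")

  ring <- analyze_field(generate_mosaic(synthetic_config("ring",
    target_density = 2500, seed = 2)))
  hom <- analyze_field(generate_mosaic(synthetic_config("homogeneous",
    target_density = 2500, seed = 2)))
  tail_mass <- function(ms) {
    mean(ms$areas_interior > 2 * stats::median(ms$areas_interior))
  }
  expect_gt(tail_mass(ring), tail_mass(hom))
})
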