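sq <- function(x0, y0, w = 1) aliendist:::square_geom(x0, y0, w)

test_that("WKT polygons and multipolygons round-trip losslessly", {
  wkts <- c(
    "POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))",
    "POLYGON ((0 0, 4 0, 4 4, 0 4, 0 0), (1 1, 2 1, 2 2, 1 2, 1 1))",
    "MULTIPOLYGON (((0 0, 1 0, 1 1, 0 1, 0 0)), ((2 0, 3 0, 3 1, 2 1, 2 0)))"
  )
  for (w in wkts) {
    g <- parse_wkt(w)
    g2 <- parse_wkt(format_wkt(g))
    expect_equal(geom_area(g), geom_area(g2), info = w)
    expect_equal(lengths(g), lengths(g2), info = w)
  }
})

test_that("area subtracts holes; points in holes are outside", {
  g <- parse_wkt("POLYGON ((0 0, 4 0, 4 4, 0 4, 0 0), (1 1, 2 1, 2 2, 1 2, 1 1))")
  expect_equal(geom_area(g), 15)
  expect_false(point_in_geom(1.5, 1.5, g))
  expect_true(point_in_geom(3, 3, g))
  expect_false(point_in_geom(5, 5, g))
})

test_that("intersection area is exact for convex clips and boundary contact is not overlap", {
  a <- sq(0, 0); b <- sq(0.5, 0.5); c <- sq(1, 0)
  expect_equal(geom_intersection_area(a, b), 0.25)
  expect_equal(geom_intersection_area(a, c), 0)
  expect_true(geom_overlaps(a, b))
  expect_false(geom_overlaps(a, c))          # shared edge only
  expect_false(geom_overlaps(sq(0, 0), sq(1, 1)))  # corner touch only
  expect_true(geom_overlaps(a, a))           # identical squares fully overlap
  expect_equal(geom_intersection_area(a, a), 1)
})

test_that("concave clip geometries fall back to grid sampling with small error", {
  conc <- parse_wkt("POLYGON ((0 0, 4 0, 4 1, 1 1, 1 3, 0 3, 0 0))")  # L-shape, area 6
  expect_false(aliendist:::geom_is_convex(conc))
  est <- geom_intersection_area(sq(0, 0, 4), conc)
  expect_lt(abs(est - 6), 0.1)
})

test_that("shrinking a feature never increases its intersection area", {
  withr::with_seed(11, {
    for (i in 1:20) {
      x0 <- runif(1, -1, 1); y0 <- runif(1, -1, 1)
      w_big <- runif(1, 0.5, 2); w_small <- w_big * runif(1, 0.2, 1)
      big <- sq(x0, y0, w_big); small <- sq(x0, y0, w_small)
      clip <- sq(runif(1, -1, 1), runif(1, -1, 1), 1)
      expect_lte(geom_intersection_area(small, clip),
                 geom_intersection_area(big, clip) + 1e-12)
    }
  })
})

test_that("degenerate geometries are invalid", {
  expect_false(geom_is_valid(parse_wkt("POLYGON ((0 0, 1 1, 0 0))")))
  expect_true(geom_is_valid(sq(0, 0)))
})

test_that("equal-area transform yields plausible spherical areas", {
  # 1-degree square at the equator is about 111.2 x 111.2 km
  a <- geom_area(sq(0, 0), equal_area = TRUE)
  expect_lt(abs(a - 111.195^2) / 111.195^2, 0.01)
  # the same square at 60 N has about half that area
  a60 <- geom_area(sq(0, 59.5), equal_area = TRUE)
  expect_lt(abs(a60 / a - cos(60 * pi / 180)) , 0.01)
})

test_that("optimal string alignment distance counts transpositions", {
  expect_equal(osa_distance("abcd", c("abcd", "abdc", "abce", "abcde", "bacd", "xyz")),
               c(0L, 1L, 1L, 1L, 1L, 4L))
})
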