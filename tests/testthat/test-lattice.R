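test_that("square lattice has exact pitch geometry", {
  lat <- fixture_lattice("square", width = 1, spacing = 1,
                         extent = c(20, 20))
  expect_equal(lat$pitch_um, 2)
  d <- as.matrix(dist(lat$centers))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(abs(nn - 2) < 1e-12))
  expect_true(all(lat$centers$x_um > 0))
})

test_that("hexagonal interior centers have six neighbours at the pitch", {
  lat <- fixture_lattice("hexagonal", width = 1, spacing = 1,
                         extent = c(30, 30))
  p <- lat$pitch_um
  d <- as.matrix(dist(lat$centers))
  diag(d) <- Inf
  interior <- lat$centers$x_um > 2 * p & lat$centers$x_um < 30 - 2 * p &
    lat$centers$y_um > 2 * p & lat$centers$y_um < 30 - 2 * p
  n6 <- rowSums(abs(d[interior, , drop = FALSE] - p) < 1e-9)
  expect_true(all(n6 == 6))
})

test_that("oversized pillars in a small field leave at most one center", {
  # independent enumeration: pitch 15.6, first center at 7.8 from border and
  # edge, so exactly one center fits a 10x10 um field in each geometry
  for (geom in c("square", "hexagonal")) {
    lat <- fixture_lattice(geom, width = 5.6, spacing = 10,
                           extent = c(10, 10))
    expect_lte(nrow(lat$centers), 1L)
    expect_equal(nrow(lat$centers), 1L)
    expect_equal(unlist(lat$centers[1, ]), c(x_um = 7.8, y_um = 7.8))
  }
})

test_that("a field too small for any pillar is an explicit error", {
  spec <- lattice_spec("square", 5.6, 10, c(5, 5), 0.1)
  expect_error(make_lattice(spec), "empty lattice")
})

test_that("invalid lattice specifications are rejected", {
  expect_error(lattice_spec("square", -1, 1, c(10, 10), 0.1))
  expect_error(lattice_spec("square", 1, 1, c(10, 10), 2), "two pixels")
})

test_that("nearest distances hit the exact geometric landmarks", {
  lat <- fixture_lattice("square", 1, 1, extent = c(20, 20))
  # on a center
  expect_equal(nearest_pillar_distances(1, 1, lat), 0)
  # center of a square cell: a / sqrt(2)
  expect_equal(nearest_pillar_distances(2, 2, lat), 2 / sqrt(2))
  # hexagonal hole (triangle centroid): a / sqrt(3)
  hex <- fixture_lattice("hexagonal", 1, 1, extent = c(20, 20))
  p <- hex$pitch_um
  hole_x <- p  # centroid of the (p/2,p/2), (3p/2,p/2), (p,p/2+h) triangle
  hole_y <- p / 2 + p * sqrt(3) / 2 / 3
  expect_equal(nearest_pillar_distances(hole_x, hole_y, hex), p / sqrt(3),
               tolerance = 1e-12)
  # empty point set
  expect_identical(nearest_pillar_distances(numeric(0), numeric(0), lat),
                   numeric(0))
})

test_that("nearest distances are invariant under joint rigid motions", {
  lat <- fixture_lattice("hexagonal", 1.6, 1.2, extent = c(25, 25))
  set.seed(11)
  x <- runif(200, 0, 25); y <- runif(200, 0, 25)
  d0 <- nearest_pillar_distances(x, y, lat)
  th <- 0.7; tx <- 3.1; ty <- -4.2
  rot <- function(px, py) list(x = cos(th) * px - sin(th) * py + tx,
                               y = sin(th) * px + cos(th) * py + ty)
  pts <- rot(x, y)
  ctr <- rot(lat$centers$x_um, lat$centers$y_um)
  lat2 <- lat
  lat2$centers <- data.frame(x_um = ctr$x, y_um = ctr$y)
  expect_equal(nearest_pillar_distances(pts$x, pts$y, lat2), d0,
               tolerance = 1e-9)
})

test_that("distance statistics are scale-equivariant", {
  for (cc in c(0.5, 3)) {
    lat1 <- fixture_lattice("square", 1, 1, extent = c(20, 20))
    lat2 <- fixture_lattice("square", cc, cc, extent = cc * c(20, 20))
    set.seed(5)
    x <- runif(100, 0, 20); y <- runif(100, 0, 20)
    expect_equal(nearest_pillar_distances(cc * x, cc * y, lat2),
                 cc * nearest_pillar_distances(x, y, lat1),
                 tolerance = 1e-9)
  }
})

test_that("closed-form lattice distance CDF matches its limits and quadrature", {
  p <- 2
  # disjoint-disk regime and saturation
  expect_equal(lattice_distance_cdf(0.5, "square", p), pi * 0.25 / 4)
  expect_equal(lattice_distance_cdf(p / sqrt(2), "square", p), 1)
  expect_equal(lattice_distance_cdf(0.5, "hexagonal", p),
               pi * 0.25 / (sqrt(3) / 2 * 4))
  expect_equal(lattice_distance_cdf(p / sqrt(3) + 1e-12, "hexagonal", p), 1)
  expect_true(all(diff(lattice_distance_cdf(seq(0, 2, 0.01), "hexagonal", p))
                  >= 0))
  # mid-range square values against a quadrature oracle on a 2000^2 grid
  g <- seq(-p / 2, p / 2, length.out = 2000)
  dmin <- sqrt(outer(g^2, g^2, "+"))
  rs <- seq(0.2, 1.4, by = 0.1)
  quad <- vapply(rs, function(r) mean(dmin <= r), numeric(1))
  expect_lt(max(abs(quad - lattice_distance_cdf(rs, "square", p))), 1e-3)
})

test_that("rotated lattices keep their pitch and stay inside the field", {
  lat <- make_lattice(lattice_spec("square", 1, 1, c(20, 20), 0.1,
                                   border_x_um = -1e9, rotation_deg = 17))
  d <- as.matrix(dist(lat$centers)); diag(d) <- Inf
  expect_true(all(abs(apply(d, 1, min) - 2) < 1e-9))
  expect_true(all(lat$centers$x_um >= 0 & lat$centers$x_um <= 20))
})
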