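test_that("plane sections of simple boxes have closed-form areas", {
  a <- 4.0
  sc <- make_toy_structure("simple_cubic", a = a)
  sec <- plane_section(sc, c(0, 0, 1), offset = a / 2)
  expect_equal(sec$area, a^2)
  ha <- make_toy_structure("ha_like")
  basal <- plane_section(ha, c(0, 0, 1), offset = 0)
  expect_equal(basal$area, 9.4^2 * sqrt(3) / 2)
  expect_equal(nrow(basal$verts2), 4L)   # basal parallelogram
})

test_that("plane-section polygons agree with a Monte-Carlo area oracle", {
  set.seed(21)
  ha <- make_toy_structure("ha_like")
  for (i in 1:10) {
    p <- sample(-3:3, 3, replace = TRUE)
    if (all(p == 0)) p <- c(1, 1, 0)
    d <- d_spacing(ha$lattice, p)
    sec <- tryCatch(plane_section(ha, p, offset = runif(1, 0.2, 0.8) * d),
                    error = function(e) NULL)
    if (is.null(sec)) next
    expect_equal(sec$area, mc_section_area(ha, sec), tolerance = 0.02)
  }
})

test_that("planes that miss the box raise an empty-section error", {
  sc <- make_toy_structure("simple_cubic")
  expect_error(plane_section(sc, c(1, 0, 0), offset = 100),
               "does not intersect")
})

test_that("circle-polygon clipping is exact in the closed-form cases", {
  sq <- rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  expect_equal(circle_polygon_area(c(0, 0), 1, sq), pi)
  # disc centered on a straight edge far from vertices: half-plane cut
  expect_equal(circle_polygon_area(c(0, -5), 1, sq), pi / 2)
  # disc fully outside
  expect_equal(circle_polygon_area(c(20, 0), 1, sq), 0)
  expect_error(circle_polygon_area(c(0, 0), 1, sq[1:2, ]), "degenerate")
})

test_that("circle-polygon clipping agrees with a Monte-Carlo oracle", {
  set.seed(22)
  for (i in 1:40) {
    P <- random_convex_polygon()
    center <- runif(2, -3, 3)
    r <- runif(1, 0.3, 2.5)
    expect_lt(abs(circle_polygon_area(center, r, P) -
                    mc_circle_polygon_area(center, r, P)),
              1e-2 * pi * r^2)
  }
})

test_that("clipped area is monotone in radius and additive under bisection", {
  set.seed(23)
  P <- random_convex_polygon()
  center <- c(0.3, -0.2)
  radii <- seq(0.1, 4, by = 0.3)
  areas <- vapply(radii, function(r) circle_polygon_area(center, r, P),
                  numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
  # bisect the polygon with a chord through two edge midpoints
  sq <- rbind(c(-2, -2), c(2, -2), c(2, 2), c(-2, 2))
  left <- rbind(c(-2, -2), c(0, -2), c(0, 2), c(-2, 2))
  right <- rbind(c(0, -2), c(2, -2), c(2, 2), c(0, 2))
  for (i in 1:20) {
    center <- runif(2, -2.5, 2.5)
    r <- runif(1, 0.2, 2)
    expect_equal(circle_polygon_area(center, r, left) +
                   circle_polygon_area(center, r, right),
                 circle_polygon_area(center, r, sq), tolerance = 1e-9)
  }
})

test_that("atom membership respects the plane tolerance and the polygon", {
  a <- 4.0
  sc <- make_toy_structure("simple_cubic", a = a)
  sec <- plane_section(sc, c(1, 0, 0), offset = 0)
  # the four face corners carry touching discs; farther images cannot overlap
  atoms <- atoms_on_plane(sc, sec, tol = 0)
  expect_equal(nrow(atoms), 4L)
  expect_true(all(abs(atoms$dist) < 1e-12))
  # an off-plane slice excludes atoms beyond the tolerance
  sec2 <- plane_section(sc, c(1, 0, 0), offset = 0.5)
  expect_equal(nrow(atoms_on_plane(sc, sec2, tol = 0.01)), 0L)
  expect_gt(nrow(atoms_on_plane(sc, sec2, tol = 0.6)), 0L)
})

test_that("textbook planar densities are reproduced exactly", {
  sc <- make_toy_structure("simple_cubic")
  rec <- planar_density(sc, c(1, 0, 0))
  expect_equal(rec$density, pi / 4, tolerance = 1e-9)
  expect_equal(rec$atoms_counted, 4L)
  fcc <- make_toy_structure("fcc_like")
  expect_equal(planar_density(fcc, c(1, 1, 1))$density, pi / (2 * sqrt(3)),
               tolerance = 1e-9)
})

test_that("planar density is invariant under supercell expansion", {
  sc <- make_toy_structure("simple_cubic")
  sc2 <- build_supercell(sc, 2)
  for (p in list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))) {
    d1 <- planar_density(sc, p)$density
    d2 <- planar_density(sc2, p)$density
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("union clipping never exceeds summed clipping and matches it for
           non-overlapping discs", {
  sc <- make_toy_structure("simple_cubic")
  plain <- planar_density(sc, c(1, 0, 0))
  merged <- planar_density(sc, c(1, 0, 0), union = TRUE)
  expect_equal(plain$density, merged$density, tolerance = 1e-9)
  # enlarge the radii so the face discs overlap
  fat <- sc
  fat$sites$radius <- 2.8
  fat <- crystal_structure(fat$sites, basis = fat$basis)
  plain <- planar_density(fat, c(1, 0, 0), offset = 0)
  merged <- planar_density(fat, c(1, 0, 0), offset = 0, union = TRUE)
  expect_lt(merged$density, plain$density)
  expect_lte(merged$density, 1 + 1e-12)
})

test_that("disc-union clipping matches a Monte-Carlo oracle", {
  set.seed(24)
  for (i in 1:10) {
    P <- random_convex_polygon()
    nd <- sample(2:4, 1)
    centers <- matrix(runif(2 * nd, -2, 2), ncol = 2)
    radii <- runif(nd, 0.5, 2)
    u <- usdmwh:::discs_union_polygon_area(centers, radii, P)
    n <- 1e5
    q <- cbind(runif(n, -4, 4), runif(n, -4, 4))
    m <- nrow(P)
    inpoly <- rep(TRUE, n)
    for (j in seq_len(m)) {
      a <- P[j, ]
      b <- P[j %% m + 1, ]
      inpoly <- inpoly & ((b[1] - a[1]) * (q[, 2] - a[2]) -
                            (b[2] - a[2]) * (q[, 1] - a[1]) >= 0)
    }
    indisc <- rep(FALSE, n)
    for (j in seq_len(nd))
      indisc <- indisc | ((q[, 1] - centers[j, 1])^2 +
                            (q[, 2] - centers[j, 2])^2 < radii[j]^2)
    expect_equal(u, mean(inpoly & indisc) * 64, tolerance = 0.05)
  }
})
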