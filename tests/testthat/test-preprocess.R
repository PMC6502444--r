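test_that("decimation honours the face-count contract", {
  ico <- crowntopo:::.icosphere(16)           # 5120 faces, closed
  expect_equal(nrow(ico$faces), 5120L)
  d <- decimate_to_count(ico, 500)
  expect_true(nrow(d$faces) >= 498 && nrow(d$faces) <= 500)

  h <- make_hemisphere(1, 2000)
  expect_identical(decimate_to_count(h, nrow(h$faces)), h)
  expect_warning(decimate_to_count(h, nrow(h$faces) + 100), "cannot simplify")
  expect_error(decimate_to_count(h, 3), class = "ct_degenerate_error")
})

test_that("decimating a smooth convex surface barely changes its area", {
  h <- make_hemisphere(1, 20000)
  d <- decimate_to_count(h, 10000)
  expect_lt(abs(surface_area(d) - surface_area(h)) / surface_area(h), 0.01)
  # decimation error shrinks with budget on the same fixture
  err <- sapply(c(500, 2000, 8000), function(n)
    abs(surface_area(decimate_to_count(h, n)) - 2 * pi) / (2 * pi))
  expect_true(all(diff(err) < 0))
})

test_that("resolution targets derive from measured surface area", {
  p <- make_plane(5, 2, 2000)                 # SA exactly 10 mm^2
  expect_equal(surface_area(p), 10)
  res <- decimate_to_resolution(p, 100)
  expect_equal(res$target_count, 1000L)
  expect_true(nrow(res$mesh$faces) <= 1000L && nrow(res$mesh$faces) >= 998L)

  p4 <- make_plane(2, 2, 100)                 # SA = 4: r = 0.5 gives target 2
  expect_error(decimate_to_resolution(p4, 0.5), class = "ct_degenerate_error")

  h <- make_hemisphere(1, 20000)
  tc <- decimate_to_resolution(h, 1000)$target_count
  expect_lt(abs(tc - round(1000 * 2 * pi)) / (1000 * 2 * pi), 0.01)
})

test_that("Laplacian smoothing obeys its invariances", {
  h <- make_hemisphere(1, 2000)
  expect_identical(smooth_mesh(h, lambda_step = 0), h)
  expect_identical(smooth_mesh(h, iterations = 0L), h)

  # a planar mesh stays exactly planar (centroids of coplanar points)
  p <- make_plane(1, 1, 100)
  ps <- smooth_mesh(p, 0.6, 25L)
  expect_identical(ps$vertices[, 3], p$vertices[, 3])
  expect_identical(ps$faces, p$faces)

  # composition: k then j iterations equals k + j in one call, bit for bit
  set.seed(9)
  noisy <- h
  noisy$vertices <- noisy$vertices * (1 + 0.02 * rnorm(nrow(noisy$vertices)))
  a <- smooth_mesh(smooth_mesh(noisy, 0.6, 30L), 0.6, 20L)
  b <- smooth_mesh(noisy, 0.6, 50L)
  expect_identical(a$vertices, b$vertices)

  # smoothing a noisy convex surface shrinks its area
  expect_lt(surface_area(smooth_mesh(noisy, 0.6, 100L)), surface_area(noisy))

  # total collapse is flagged, not silent
  expect_warning(out <- smooth_mesh(make_tetra(), 0.6, 100L),
                 "zero projected extent")
  expect_true(isTRUE(attr(out, "ct_destroyed")))
})

test_that("plane cropping splits faces exactly at the cut height", {
  h <- make_hemisphere(1, 20000)
  expect_identical(crop_bco(h, -0.5), h)      # plane below the mesh
  expect_identical(crop_bco(h, 0), h)         # boundary already at 0
  expect_error(crop_bco(h, 2), class = "ct_degenerate_error")

  cap <- crop_bco(h, 0.5)
  expect_gte(min(cap$vertices[, 3]), 0.5 - 1e-9)
  # spherical cap area 2 * pi * r * h = pi for r = 1, h = 0.5
  expect_lt(abs(surface_area(cap) - pi) / pi, 0.02)
  # cut boundary lies exactly on the plane
  bv <- crowntopo:::boundary_vertices(cap)
  expect_true(all(abs(cap$vertices[bv, 3] - 0.5) < 1e-9))
})

test_that("the basin plane estimate finds interior minima", {
  # dome with a single interior pit of known depth
  p <- make_plane(2, 2, 800)
  x <- p$vertices[, 1] - 1
  y <- p$vertices[, 2] - 1
  z <- 1 - (x^2 + y^2) / 2
  pit <- which.min(x^2 + y^2)
  z[pit] <- -0.5
  dome <- ct_mesh(cbind(x, y, z), p$faces)
  expect_equal(estimate_basin_plane(dome, 0.25), -0.5)

  # monotone dome: the interior minimum, not the rim value
  z2 <- 1 - (x^2 + y^2) / 2
  dome2 <- ct_mesh(cbind(x, y, z2), p$faces)
  est <- estimate_basin_plane(dome2, 0.25)
  expect_gt(est, min(z2))                     # rim excluded by the margin
  # hull of the square grid is the square; shrunk by 0.25 it is |x|,|y| <= 0.75
  inside <- abs(x) <= 0.75 + 1e-9 & abs(y) <= 0.75 + 1e-9
  expect_equal(est, min(z2[inside]))

  # zero margin on a hemisphere keeps the full outline: global minimum 0
  h <- make_hemisphere(1, 2000)
  expect_equal(estimate_basin_plane(h, 0), 0)
})
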