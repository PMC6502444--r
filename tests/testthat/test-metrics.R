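test_that("surface and projected areas are exact on polygonal fixtures", {
  sq <- ct_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_identical(surface_area(sq), 1)
  expect_equal(projected_area(sq), 1)

  big <- sq
  big$vertices <- big$vertices * 2
  expect_identical(surface_area(big), 4)

  # tilted plane: 3D area exceeds the projection by 1 / cos(angle)
  tilt <- sq
  tilt$vertices[, 3] <- tilt$vertices[, 1]    # 45 degrees
  expect_equal(surface_area(tilt), sqrt(2))
  expect_equal(projected_area(tilt), 1)

  # overlapping projections count once: two stacked unit squares
  two <- ct_mesh(rbind(sq$vertices, cbind(sq$vertices[, 1:2], 1)),
                 rbind(sq$faces, sq$faces + 4L))
  expect_equal(projected_area(two), 1)

  # vertical fin projects to nothing and is flagged degenerate
  fin <- ct_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
                 rbind(c(1, 2, 3), c(1, 3, 4)))
  pa <- projected_area(fin)
  expect_equal(as.numeric(pa), 0)
  expect_true(isTRUE(attr(pa, "ct_degenerate")))
})

test_that("relief index follows its closed form and refuses a zero outline", {
  expect_identical(rfi(3, 3), 0)
  expect_equal(rfi(2, 1), 0.34657, tolerance = 1e-4)
  expect_equal(rfi(2, 1), 0.5 * log(2))
  expect_error(rfi(1, 0), class = "ct_undefined_metric_error")
  expect_error(rfi(NA, 1), class = "ct_undefined_metric_error")
})

test_that("Dirichlet normal energy vanishes on planes and is scale invariant", {
  p <- make_plane(1, 1, 200)
  expect_equal(as.numeric(dne(p)), 0)

  cusps <- data.frame(x = c(0.8, -0.8), y = c(0.5, -0.5), height = 1, sigma = 0.5)
  m <- make_crown(crown_params(cusps = cusps, noise_sd = 0, target_faces = 2000))
  d1 <- as.numeric(dne(m))
  m2 <- m
  m2$vertices <- m2$vertices * 3.7
  expect_equal(as.numeric(dne(m2)), d1, tolerance = 1e-9)

  # outlier removal can only reduce the sum
  d_none <- as.numeric(dne(m, dne_options(outlier_energy_fraction = 0)))
  d_trim <- as.numeric(dne(m, dne_options(outlier_energy_fraction = 0.01)))
  expect_lte(d_trim, d_none)

  # boundary exclusion also only removes energy
  d_all <- as.numeric(dne(m, dne_options(0, exclude_boundary_faces = FALSE)))
  expect_lte(d_none, d_all)
})

test_that("DNE approaches the analytic hemisphere limit", {
  h <- make_hemisphere(1, 20000)
  d <- as.numeric(dne(h, dne_options(outlier_energy_fraction = 0,
                                     exclude_boundary_faces = TRUE)))
  expect_lt(abs(d - 4 * pi) / (4 * pi), 0.05)
})

test_that("orientation patch counting applies the bin and patch-size rules", {
  py <- make_pyramid(subdivisions = 2L)       # 4 slant faces x 4 triangles
  expect_identical(opc(py), 4L)
  expect_identical(opc(rotate_z(py, 45)), 4L) # bins permute under 45 degrees
  expect_identical(opc(make_plane(1, 1, 64)), 0L)

  # an isolated 2-face tilted patch stays below the minimum patch size
  p <- make_plane(1, 1, 128)
  z <- p$vertices[, 3]
  corner <- which.min(p$vertices[, 1] + p$vertices[, 2])
  z[corner] <- 0.3                            # tilts the two incident faces
  tilted <- ct_mesh(cbind(p$vertices[, 1:2], z), p$faces)
  expect_identical(opc(tilted), 0L)
  expect_gte(opc(tilted, opcr_options(min_patch_size = 1L)), 1L)
})

test_that("OPCR is the mean over sub-bin rotations and respects symmetry", {
  py <- make_pyramid(subdivisions = 3L)
  o <- opcr(py)
  per <- attr(o, "per_rotation")
  expect_length(per, 8L)
  expect_equal(as.numeric(o), mean(per))

  # a cone with 64-fold symmetry gives the same OPC at every 5.625-degree step
  cone <- make_cone(n_seg = 64L, n_rings = 6L)
  oc <- opcr(cone)
  expect_true(all(attr(oc, "per_rotation") == attr(oc, "per_rotation")[1]))
  expect_equal(as.numeric(oc), attr(oc, "per_rotation")[1])
})

test_that("ambient occlusion grades exposure and is sampling-consistent", {
  p <- make_plane(1, 1, 100)
  expect_true(all(pcv_field(p, pcv_options(64L)) == 1))

  # erecting a wall next to a plane strictly lowers visibility nearby
  base <- make_plane(2, 2, 200)
  wall <- make_well(half = 1, height = 2, n = 4L)
  near <- which.min(rowSums(sweep(base$vertices, 2, c(1, 1, 0))^2))
  combo <- ct_mesh(rbind(base$vertices, wall$vertices),
                   rbind(base$faces, wall$faces + nrow(base$vertices)))
  f_open <- pcv_field(base, pcv_options(128L))
  f_wall <- pcv_field(combo, pcv_options(128L))
  expect_lt(f_wall[near], f_open[near])

  # direction-count consistency on a convex fixture
  h <- make_hemisphere(1, 1500)
  f64 <- pcv_field(h, pcv_options(64L))
  f1024 <- pcv_field(h, pcv_options(1024L))
  expect_lt(mean(abs(f64 - f1024)), 0.05)
})

test_that("mean PCV averages the field and tracks the area-weighted mean", {
  expect_equal(pcv_mean(c(1, 1, 0)), 2 / 3, tolerance = 1e-4)
  expect_identical(pcv_mean(rep(0.42, 10)), 0.42)
  expect_error(pcv_mean(numeric()), class = "ct_validation_error")

  h <- make_hemisphere(1, 2000)
  f <- pcv_field(h, pcv_options(128L))
  va <- crowntopo:::tapply_sum(rep(crowntopo:::face_areas(h) / 3, 3),
                               as.vector(h$faces), nrow(h$vertices))
  expect_lt(abs(pcv_mean(f) - sum(f * va) / sum(va)) / pcv_mean(f), 0.02)
})

test_that("the assembled metric set is consistent and honest about failures", {
  h <- make_hemisphere(1, 5000)
  ms <- compute_metrics(h, pcv_opts = pcv_options(64L))
  expect_s3_class(ms, "ct_metric_set")
  expect_equal(ms$rfi, 0.3466, tolerance = 0.01)
  expect_gte(ms$surface_area, ms$tooth_size)
  expect_equal(ms$resolution, ms$triangle_count / ms$surface_area)

  # destroyed outline: RFI missing with a reason, other metrics intact
  fin <- ct_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
                 rbind(c(1, 2, 3), c(1, 3, 4)))
  mf <- compute_metrics(fin, metrics = c("dne", "rfi", "surface_area", "tooth_size"))
  expect_true(is.na(mf$rfi))
  expect_true("rfi" %in% names(attr(mf, "reasons")))
  expect_equal(mf$surface_area, 1)

  # surface area dominates the projection on every synthetic crown
  co <- make_cohort(2, seed = 3, target_faces = 1500)
  for (m in co$meshes) {
    sa <- surface_area(m)
    expect_gte(sa, as.numeric(projected_area(m)))
  }
})
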