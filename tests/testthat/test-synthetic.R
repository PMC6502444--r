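test_that("analytic fixtures hit their closed forms", {
  p <- make_plane(1, 1, 2)
  expect_equal(nrow(p$faces), 2L)
  expect_identical(surface_area(p), 1)
  expect_equal(projected_area(p), 1)
  expect_equal(as.numeric(dne(p)), 0)

  h <- make_hemisphere(1, 2000)
  expect_gte(nrow(h$faces), 2000L)
  expect_lt(abs(surface_area(h) - 2 * pi) / (2 * pi), 0.01)
  expect_lt(abs(projected_area(h) - pi) / pi, 0.01)
  expect_lt(abs(rfi(surface_area(h), projected_area(h)) - 0.5 * log(2)) /
              (0.5 * log(2)), 0.02)

  py <- make_pyramid(subdivisions = 2L)
  expect_equal(nrow(py$faces), 16L)           # 4 slant faces x 4 triangles
  expect_identical(opc(py), 4L)
})

test_that("fixture metrics converge toward the analytic limits with budget", {
  errs <- sapply(c(500, 2000, 8000), function(n) {
    h <- make_hemisphere(1, n)
    abs(surface_area(h) - 2 * pi) / (2 * pi)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("the default crown dome matches the spherical-cap energy integral", {
  pr <- crown_params(base_radius = 2.5, base_height = 1.2, noise_sd = 0,
                     target_faces = 8000)
  dome <- make_crown(pr)
  rs <- (2.5^2 + 1.2^2) / (2 * 1.2)           # cap sphere radius
  analytic <- 4 * pi * 1.2 / rs               # (2 / rs^2) * cap area
  d <- as.numeric(dne(dome, dne_options(outlier_energy_fraction = 0)))
  expect_lt(abs(d - analytic) / analytic, 0.1)
})

test_that("crown generation is deterministic and monotone in cusp height", {
  cusps <- data.frame(x = c(1, -1), y = c(0.8, -0.8), height = 1, sigma = 0.4)
  a <- make_crown(crown_params(cusps = cusps, seed = 5, target_faces = 3000))
  b <- make_crown(crown_params(cusps = cusps, seed = 5, target_faces = 3000))
  expect_identical(a, b)
  c2 <- make_crown(crown_params(cusps = cusps, seed = 6, target_faces = 3000))
  expect_false(identical(a$vertices, c2$vertices))

  tall <- cusps
  tall$height <- 2
  m1 <- make_crown(crown_params(cusps = cusps, noise_sd = 0, target_faces = 3000))
  m2 <- make_crown(crown_params(cusps = tall, noise_sd = 0, target_faces = 3000))
  expect_gt(surface_area(m2), surface_area(m1))
  expect_gt(rfi(surface_area(m2), projected_area(m2)),
            rfi(surface_area(m1), projected_area(m1)))
})

test_that("cohorts are labelled, reproducible in schema, and complete", {
  co <- make_cohort(2, seed = 7, target_faces = 1200)
  expect_length(co$meshes, 10L)               # 5 diets x 2
  expect_equal(nrow(co$manifest), 10L)
  expect_setequal(unique(co$manifest$diet), diet_presets()$diet)

  co2 <- make_cohort(2, seed = 8, target_faces = 1200)
  expect_identical(names(co2$manifest), names(co$manifest))
  expect_false(identical(co$meshes[[1]]$vertices, co2$meshes[[1]]$vertices))

  dir <- withr::local_tempdir()
  co3 <- make_cohort(2, seed = 7, target_faces = 1200, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.ply$"), 10L)
  back <- read_ply(file.path(dir, "insectivore_01.ply"))
  expect_equal(unname(back$vertices), unname(co3$meshes$insectivore_01$vertices))
})

test_that("the cohort pipeline runs end to end without missing metrics", {
  co <- make_cohort(2, seed = 9, target_faces = 3000)
  m <- co$meshes[[3]]
  crop <- crop_bco(m, estimate_basin_plane(m))
  lvl <- decimate_to_count(crop, 1000)
  sm <- smooth_mesh(lvl, 0.6, 50L)
  ms <- compute_metrics(sm, pcv_opts = pcv_options(64L))
  expect_true(all(is.finite(unlist(ms[1, ]))))
  expect_length(attr(ms, "reasons"), 0L)
})
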