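test_that("ASCII PLY files parse, including fan-triangulated quads", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 2",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "3 0 1 2", "3 0 2 3"), f)
  m <- read_ply(f)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 2L)
  expect_equal(m$vertices[2, ], c(x = 1, y = 0, z = 0))

  # a single quad face fan-splits into two triangles at its first vertex
  fq <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 1",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "4 0 1 2 3"), fq)
  mq <- read_ply(fq)
  expect_equal(mq$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("PLY round-trips are exact and binary output is byte-stable", {
  set.seed(3)
  m <- ct_mesh(matrix(rnorm(30), 10, 3),
               t(replicate(6, sample(10, 3))),
               fields = list(pcv = runif(10)))
  fb <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, fb, "binary_le")
  m2 <- read_ply(fb)
  expect_identical(unname(m$vertices), unname(m2$vertices))
  expect_identical(m$faces, m2$faces)
  expect_identical(m$fields$pcv, unname(m2$fields$pcv))

  fb2 <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, fb2, "binary_le")
  expect_identical(readBin(fb, "raw", file.size(fb)),
                   readBin(fb2, "raw", file.size(fb2)))

  fa <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, fa, "ascii")
  m3 <- read_ply(fa)
  expect_equal(unname(m3$vertices), unname(m$vertices), tolerance = 1e-15)
  # the ascii face-count line states the number of faces
  expect_true(any(grepl("^element face 6$", readLines(fa, n = 12))))
})

test_that("malformed PLY input is rejected with format errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 10",
    "property float x", "property float y", "property float z",
    "element face 1",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "3 0 1 2"), f)  # declares 10 vertices, supplies 4
  expect_error(read_ply(f), class = "ct_format_error")

  fb <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_big_endian 1.0", "end_header"), fb)
  expect_error(read_ply(fb), "big-endian", class = "ct_format_error")

  # truncated binary payload names a byte offset
  m <- make_plane(1, 1, 8)
  ft <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, ft, "binary_le")
  raw <- readBin(ft, "raw", file.size(ft))
  writeBin(raw[1:(length(raw) - 10L)], ft)
  expect_error(read_ply(ft), "byte", class = "ct_format_error")

  # non-finite vertices refuse to write
  bad <- ct_mesh(rbind(c(0, 0, NaN), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_error(write_ply(bad, withr::local_tempfile(fileext = ".ply")),
               class = "ct_validation_error")
})

test_that("validation cleans degeneracies and reports honest bookkeeping", {
  ico <- crowntopo:::.icosphere(1)
  r <- validate_mesh(ico)$report
  expect_equal(r$n_vertices, 12L)
  expect_equal(r$n_faces, 20L)
  expect_equal(r$euler_characteristic, 2L)   # closed surface: V - E + F = 2
  expect_equal(r$n_boundary_edges, 0L)

  # a zero-area (collinear) face is counted and removed
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))        # second face is collinear
  out <- validate_mesh(ct_mesh(v, f))
  expect_equal(out$report$n_degenerate, 1L)
  expect_equal(out$report$n_faces, 1L)

  # vertices 1e-9 apart weld at the default 1e-6 tolerance
  v2 <- rbind(c(0, 0, 0), c(0, 0, 1e-9), c(1, 0, 0), c(0, 1, 0))
  f2 <- rbind(c(1, 3, 4), c(2, 4, 3))
  out2 <- validate_mesh(ct_mesh(v2, f2))
  expect_equal(out2$report$n_vertices, 3L)

  # brute-force check: no surviving vertex pair is within the weld tolerance
  d <- as.matrix(dist(out2$mesh$vertices))
  diag(d) <- Inf
  expect_true(min(d) > 1e-6)

  # idempotent: validating a validated mesh changes nothing
  again <- validate_mesh(out2$mesh)
  expect_identical(again$mesh, out2$mesh)
  expect_equal(again$report$n_degenerate, 0L)

  expect_error(validate_mesh(ct_mesh(v, rbind(c(1, 2, 4)))),  # collinear only
               class = "ct_degenerate_error")
})

test_that("occlusal orientation is asserted and the flip is an involution", {
  up <- make_hemisphere(1, 300)
  expect_identical(orient_occlusal(up), up)

  down <- up
  down$vertices[, 2] <- -down$vertices[, 2]
  down$vertices[, 3] <- -down$vertices[, 3]
  expect_error(orient_occlusal(down), class = "ct_orientation_error")

  fixed <- orient_occlusal(down, flip = TRUE)
  expect_equal(fixed$vertices, up$vertices)
  # applying the 180-degree rotation twice is the identity on coordinates
  refl <- fixed
  refl$vertices[, 2] <- -refl$vertices[, 2]
  refl$vertices[, 3] <- -refl$vertices[, 3]
  expect_identical(refl$vertices, down$vertices)
})
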