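# Deterministic synthetic fixtures: analytic shapes with closed-form metric
# values (plane, hemisphere, cone, pyramid) and parametric multi-cusp crowns
# with dietary presets, standing in for scanned molars in tests and studies.

#' Triangulated rectangular plane
#'
#' A flat grid in the z = 0 plane. Analytic values: surface area
#' `width * depth`, projected area the same, DNE 0, OPC 0 (all normals
#' vertical), PCV 1 (nothing occludes the sky).
#'
#' @param width,depth extents in mm.
#' @param target_faces approximate triangle budget (`>= 2`).
#' @export
make_plane <- function(width = 1, depth = 1, target_faces = 2L) {
  stopifnot(width > 0, depth > 0, target_faces >= 2L)
  nx <- max(1L, round(sqrt(target_faces / 2 * width / depth)))
  ny <- max(1L, round(target_faces / (2 * nx)))
  xs <- seq(0, width, length.out = nx + 1L)
  ys <- seq(0, depth, length.out = ny + 1L)
  v <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L), 0)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  ct_mesh(v, f)
}

# Unit icosahedron subdivided k-fold per edge and projected to the sphere.
# Shared-edge points are bitwise identical across faces (commutative integer
# barycentric sums), so exact welding is safe.
.icosphere <- function(k, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(1 + t^2)
  f <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))

  verts <- list()
  faces <- list()
  for (fi in seq_len(nrow(f))) {
    A <- v[f[fi, 1L], ]; B <- v[f[fi, 2L], ]; C <- v[f[fi, 3L], ]
    # grid point (i, j): weight (k - i - j, i, j) / k
    pt_id <- matrix(NA_integer_, k + 1L, k + 1L)
    for (i in 0:k) for (j in 0:(k - i)) {
      p <- ((k - i - j) * A + i * B + j * C) / k
      verts[[length(verts) + 1L]] <- p
      pt_id[i + 1L, j + 1L] <- length(verts)
    }
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L - i)) {
      faces[[length(faces) + 1L]] <-
        c(pt_id[i + 1L, j + 1L], pt_id[i + 2L, j + 1L], pt_id[i + 1L, j + 2L])
      if (i + j <= k - 2L)
        faces[[length(faces) + 1L]] <-
          c(pt_id[i + 2L, j + 1L], pt_id[i + 2L, j + 2L], pt_id[i + 1L, j + 2L])
    }
  }
  V <- do.call(rbind, verts)
  Fm <- matrix(unlist(faces), ncol = 3L, byrow = TRUE)
  key <- apply(V, 1L, function(r) paste(r, collapse = "|"))
  first <- match(key, key)
  remap <- match(first, unique(first))
  V <- V[unique(first), , drop = FALSE]
  Fm <- matrix(remap[Fm], ncol = 3L)
  V <- V / sqrt(rowSums(V^2)) * radius
  mesh <- ct_mesh(V, Fm)
  # ensure outward winding
  if (mean(rowSums(face_normals(mesh) *
                   (V[Fm[, 1L], ] + V[Fm[, 2L], ] + V[Fm[, 3L], ]) / 3)) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Triangulated hemisphere
#'
#' The upper half of a subdivided icosphere, cut exactly at z = 0, open at
#' the base. Analytic limits as `target_faces` grows: surface area
#' `2 * pi * r^2`, projected area `pi * r^2`, RFI `ln(sqrt(2)) ~ 0.3466`,
#' DNE `4 * pi`.
#'
#' @param radius radius in mm.
#' @param target_faces minimum triangle budget (`>= 4`); the construction
#'   overshoots slightly rather than undershooting.
#' @export
make_hemisphere <- function(radius = 1, target_faces = 500L) {
  stopifnot(radius > 0, target_faces >= 4L)
  k <- max(1L, ceiling(sqrt(target_faces / 10)))
  crop_bco(.icosphere(k, radius), 0)
}

#' Triangulated open cone
#'
#' An upright cone (apex up, open base) with `n_seg`-fold rotational
#' symmetry. With `n_seg` a multiple of `n_bins * n_rotations`, OPC is
#' identical at every OPCR rotation.
#'
#' @param radius,height base radius and apex height in mm.
#' @param n_seg angular segments (default 64).
#' @param n_rings radial subdivisions from apex to base rim.
#' @export
make_cone <- function(radius = 1, height = 1, n_seg = 64L, n_rings = 8L) {
  stopifnot(radius > 0, height > 0, n_seg >= 3L, n_rings >= 1L)
  ang <- (seq_len(n_seg) - 1L) / n_seg * 2 * pi
  verts <- list(c(0, 0, height))
  for (j in seq_len(n_rings)) {
    rj <- radius * j / n_rings
    zj <- height * (1 - j / n_rings)
    verts[[length(verts) + 1L]] <- cbind(rj * cos(ang), rj * sin(ang), zj)
  }
  V <- do.call(rbind, verts)
  ring <- function(j) 1L + (j - 1L) * n_seg + seq_len(n_seg)  # +1 for apex
  nxt <- c(2:n_seg, 1L)
  f <- cbind(1L, ring(1L), ring(1L)[nxt])
  if (n_rings > 1L) for (j in seq_len(n_rings - 1L)) {
    a <- ring(j); b <- ring(j + 1L)
    f <- rbind(f,
               cbind(a, b, b[nxt]),
               cbind(a, b[nxt], a[nxt]))
  }
  ct_mesh(V, f)
}

#' Triangulated square pyramid
#'
#' Four slant faces (open base), each subdivided into `subdivisions^2`
#' triangles. With the base edges axis-aligned, the four slant normals point
#' along +x, +y, -x, -y: the centres of four of the eight standard azimuth
#' bins, so OPC = 4 once each face has at least `min_patch_size` triangles.
#'
#' @param base base edge length in mm.
#' @param height apex height in mm.
#' @param subdivisions per-edge subdivision of each slant face (default 2,
#'   i.e. 4 triangles per face).
#' @export
make_pyramid <- function(base = 1, height = 1, subdivisions = 2L) {
  stopifnot(base > 0, height > 0, subdivisions >= 1L)
  h <- base / 2
  apex <- c(0, 0, height)
  corners <- rbind(c(h, -h, 0), c(h, h, 0), c(-h, h, 0),
                   c(-h, -h, 0), c(h, -h, 0))
  verts <- list()
  faces <- list()
  k <- subdivisions
  for (s in 1:4) {
    A <- apex; B <- corners[s, ]; C <- corners[s + 1L, ]
    pt_id <- matrix(NA_integer_, k + 1L, k + 1L)
    for (i in 0:k) for (j in 0:(k - i)) {
      p <- ((k - i - j) * A + i * B + j * C) / k
      verts[[length(verts) + 1L]] <- p
      pt_id[i + 1L, j + 1L] <- length(verts)
    }
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L - i)) {
      faces[[length(faces) + 1L]] <-
        c(pt_id[i + 1L, j + 1L], pt_id[i + 2L, j + 1L], pt_id[i + 1L, j + 2L])
      if (i + j <= k - 2L)
        faces[[length(faces) + 1L]] <-
          c(pt_id[i + 2L, j + 1L], pt_id[i + 2L, j + 2L], pt_id[i + 1L, j + 2L])
    }
  }
  V <- do.call(rbind, verts)
  Fm <- matrix(unlist(faces), ncol = 3L, byrow = TRUE)
  key <- apply(V, 1L, function(r) paste(r, collapse = "|"))
  first <- match(key, key)
  remap <- match(first, unique(first))
  V <- V[unique(first), , drop = FALSE]
  Fm <- matrix(remap[Fm], ncol = 3L)
  mesh <- ct_mesh(V, Fm)
  if (mean(face_normals(mesh)[, 3L]) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Parametric crown specification
#'
#' A crown is a height field over a disk: a base dome of height `base_height`
#' over a disk of radius `base_radius`, plus one Gaussian bump per cusp,
#' minus an optional central basin (occlusal fossa) depression, plus optional
#' vertical vertex noise. Height fields cannot overhang, which keeps the
#' projected outline exact and matches occlusal-up crown geometry.
#'
#' With `wall_exponent = 2` (the default) the dome is the exact spherical cap
#' through the rim, the analytically convenient shape. Larger exponents give
#' `z = base_height * sqrt(1 - (rho / base_radius)^p)`: a flat occlusal table
#' with steep cervical walls, the silhouette of a real enamel cap. Only with
#' steep walls and a genuine central basin does basin cut-off cropping remove
#' much surface area while barely shrinking the outline, as it does on real
#' molars.
#'
#' @param base_radius disk radius, mm.
#' @param base_height dome height at the centre, mm.
#' @param cusps data frame with columns `x`, `y` (centre, inside the base
#'   disk), `height` (mm) and `sigma` (Gaussian width, mm, positive).
#' @param noise_sd sd of vertical vertex noise in mm (0 disables).
#' @param seed integer seed controlling the noise; the same params + seed
#'   always give bit-identical meshes.
#' @param target_faces triangle budget of the finished crown.
#' @param wall_exponent dome profile exponent `p >= 2`; 2 = spherical cap.
#' @param basin_depth depth of the central fossa depression, mm (0 disables).
#' @param basin_sigma Gaussian width of the fossa, mm.
#' @param noise_wavelength range (mm) of the spatial wavelengths of the
#'   surface noise; noise is a seeded band-limited random field evaluated at
#'   each vertex, the spatial scale a surface scanner's noise actually has.
#' @export
crown_params <- function(base_radius = 2.5, base_height = 1.2,
                         cusps = NULL, noise_sd = 0.02, seed = 1L,
                         target_faces = 20000L, wall_exponent = 2,
                         basin_depth = 0, basin_sigma = base_radius / 2,
                         noise_wavelength = c(0.2, 0.6)) {
  cusps <- cusps %||% data.frame(x = numeric(), y = numeric(),
                                 height = numeric(), sigma = numeric())
  stopifnot(base_radius > 0, base_height > 0, noise_sd >= 0, target_faces >= 100L,
            wall_exponent >= 2, basin_depth >= 0, basin_sigma > 0,
            all(c("x", "y", "height", "sigma") %in% names(cusps)))
  if (nrow(cusps)) {
    stopifnot(all(cusps$sigma > 0),
              all(cusps$x^2 + cusps$y^2 <= base_radius^2))
  }
  stopifnot(length(noise_wavelength) == 2L, all(noise_wavelength > 0))
  list(base_radius = base_radius, base_height = base_height, cusps = cusps,
       noise_sd = noise_sd, seed = as.integer(seed),
       target_faces = as.integer(target_faces),
       wall_exponent = wall_exponent, basin_depth = basin_depth,
       basin_sigma = basin_sigma, noise_wavelength = noise_wavelength)
}

#' Generate a parametric multi-cusp crown
#'
#' Builds the height field of [crown_params()] on a square grid restricted to
#' the base disk (about 1.5x the requested budget), then decimates to
#' `target_faces`. Deterministic for identical params and seed.
#'
#' @param params a [crown_params()] list.
#' @return an occlusal-up [ct_mesh()].
#' @export
make_crown <- function(params) {
  R <- params$base_radius
  b <- params$base_height
  raw_target <- round(1.5 * params$target_faces)
  h <- R * sqrt(2 * pi / raw_target)
  g <- seq(-R, R, by = h)
  nx <- length(g)
  xy <- cbind(rep(g, times = nx), rep(g, each = nx))
  rho2 <- xy[, 1L]^2 + xy[, 2L]^2
  inside <- rho2 <= R^2

  p <- params$wall_exponent
  if (p == 2) {
    # spherical cap: sphere of radius rs through the rim, height b at rho=0
    rs <- (R^2 + b^2) / (2 * b)
    z <- ifelse(inside, sqrt(pmax(rs^2 - rho2, 0)) - (rs - b), 0)
  } else {
    z <- ifelse(inside, b * sqrt(pmax(1 - (sqrt(rho2) / R)^p, 0)), 0)
  }
  if (params$basin_depth > 0)
    z <- z - inside * params$basin_depth * exp(-rho2 / (2 * params$basin_sigma^2))
  if (nrow(params$cusps)) for (ci in seq_len(nrow(params$cusps))) {
    cu <- params$cusps[ci, ]
    z <- z + inside * cu$height *
      exp(-((xy[, 1L] - cu$x)^2 + (xy[, 2L] - cu$y)^2) / (2 * cu$sigma^2))
  }
  if (params$noise_sd > 0) {
    # Band-limited surface noise: a sum of random plane waves with physical
    # wavelengths in params$noise_wavelength (mm). Scanner noise has a
    # spatial scale; white per-vertex noise would instead make roughness grow
    # without bound as the mesh is refined (a coastline-paradox artefact).
    K <- 48L
    waves <- with_local_seed(params$seed, list(
      theta = stats::runif(K, 0, 2 * pi),
      lambda = stats::runif(K, params$noise_wavelength[1L],
                            params$noise_wavelength[2L]),
      phase = stats::runif(K, 0, 2 * pi)))
    field <- 0
    for (k in seq_len(K)) {
      om <- 2 * pi / waves$lambda[k]
      field <- field + cos(om * (cos(waves$theta[k]) * xy[, 1L] +
                                 sin(waves$theta[k]) * xy[, 2L]) +
                           waves$phase[k])
    }
    z <- z + inside * params$noise_sd * sqrt(2 / K) * field
  }

  id <- matrix(seq_len(nx * nx), nx, nx)           # id[ix, iy]
  ins <- matrix(inside, nx, nx)
  fs <- list()
  for (iy in seq_len(nx - 1L)) {
    ix <- which(ins[seq_len(nx - 1L), iy] & ins[-1L, iy] &
                ins[seq_len(nx - 1L), iy + 1L] & ins[-1L, iy + 1L])
    if (!length(ix)) next
    a <- id[ix, iy]; bq <- id[ix + 1L, iy]
    c2 <- id[ix + 1L, iy + 1L]; d <- id[ix, iy + 1L]
    fs[[length(fs) + 1L]] <- rbind(cbind(a, bq, c2), cbind(a, c2, d))
  }
  Fm <- do.call(rbind, fs)
  used <- sort(unique(as.vector(Fm)))
  mesh <- ct_mesh(cbind(xy, z)[used, , drop = FALSE],
                  matrix(match(Fm, used), ncol = 3L))
  if (n_faces(mesh) > params$target_faces)
    mesh <- decimate_to_count(mesh, params$target_faces)
  mesh
}

#' Dietary presets for synthetic cohorts
#'
#' Ordinal contrasts only: relative cusp height and sharpness (1/sigma)
#' decrease from insectivore through folivore, omnivore and frugivore to
#' hard-object feeder, reproducing the qualitative gradient in which
#' insectivores and folivores carry relatively taller, sharper cusps (and so
#' higher relief and curvature) than frugivores and hard-object feeders.
#' Absolute values are not calibrated to any real taxon.
#'
#' @return data frame of per-diet parameter ranges.
#' @export
diet_presets <- function() {
  data.frame(
    diet = c("insectivore", "folivore", "omnivore", "frugivore", "hard_object"),
    cusp_min = c(4L, 4L, 4L, 3L, 2L),
    cusp_max = c(6L, 5L, 5L, 4L, 4L),
    rel_height_min = c(0.60, 0.45, 0.32, 0.20, 0.08),
    rel_height_max = c(0.75, 0.58, 0.42, 0.28, 0.16),
    sharp_min = c(6.5, 5.0, 3.8, 2.8, 1.8),
    sharp_max = c(8.5, 6.3, 4.8, 3.6, 2.6),
    stringsAsFactors = FALSE
  )
}

#' Generate a labelled synthetic cohort
#'
#' Samples crown parameters per dietary preset (cusp count, relative height
#' and sharpness uniform within the preset range; cusp centres on a ring at
#' half the base radius with jitter) and builds the crowns. Cohort crowns use
#' the enamel-cap dome profile (steep cervical walls, `wall_exponent = 8`)
#' with a central fossa (`basin_depth = base_height / 2`), so basin cut-off
#' cropping behaves as it does on real molars. Deterministic given `seed`.
#'
#' @param n_per_diet crowns per diet (`>= 2`).
#' @param presets preset table as from [diet_presets()].
#' @param seed master seed; per-crown seeds are derived from it.
#' @param base_radius,base_height,noise_sd,target_faces shared crown settings.
#' @param wall_exponent,basin_depth,basin_sigma dome profile, see
#'   [crown_params()].
#' @param out_dir if non-NULL, write each crown as PLY plus a `manifest.csv`.
#' @return list with `meshes` (named list of [ct_mesh()]) and `manifest`
#'   (data frame: specimen_id, diet, n_cusps, rel_height, sharpness, seed).
#' @export
make_cohort <- function(n_per_diet, presets = diet_presets(), seed = 1L,
                        base_radius = 2.5, base_height = 1.2,
                        noise_sd = 0.02, target_faces = 20000L,
                        wall_exponent = 8, basin_depth = base_height / 2,
                        basin_sigma = base_radius * 0.45,
                        out_dir = NULL) {
  stopifnot(n_per_diet >= 2L)
  meshes <- list()
  rows <- list()
  counter <- 0L
  for (d in seq_len(nrow(presets))) {
    pr <- presets[d, ]
    for (i in seq_len(n_per_diet)) {
      counter <- counter + 1L
      crown_seed <- (as.integer(seed) * 7919L + counter * 104729L) %% 2147483647L
      draw <- with_local_seed(crown_seed, {
        nc <- sample(pr$cusp_min:pr$cusp_max, 1L)
        relh <- stats::runif(1L, pr$rel_height_min, pr$rel_height_max)
        sharp <- stats::runif(1L, pr$sharp_min, pr$sharp_max)
        ang <- stats::runif(1L, 0, 2 * pi) + (seq_len(nc) - 1L) / nc * 2 * pi
        rad <- base_radius * stats::runif(nc, 0.42, 0.55)
        list(nc = nc, relh = relh, sharp = sharp,
             cx = rad * cos(ang), cy = rad * sin(ang))
      })
      cusps <- data.frame(x = draw$cx, y = draw$cy,
                          height = draw$relh * base_radius,
                          sigma = base_radius / draw$sharp)
      id <- sprintf("%s_%02d", pr$diet, i)
      params <- crown_params(base_radius, base_height, cusps,
                             noise_sd, crown_seed, target_faces,
                             wall_exponent = wall_exponent,
                             basin_depth = basin_depth,
                             basin_sigma = basin_sigma)
      meshes[[id]] <- make_crown(params)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = id, diet = pr$diet, n_cusps = draw$nc,
        rel_height = draw$relh, sharpness = draw$sharp, seed = crown_seed,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(meshes))
      write_ply(meshes[[id]], file.path(out_dir, paste0(id, ".ply")))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(meshes = meshes, manifest = manifest)
}
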