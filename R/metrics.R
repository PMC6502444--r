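# The six per-surface measurements of dental topography:
#   DNE  - Dirichlet normal energy: surface-integrated energy of the normal
#          map; curvature/sharpness, scale invariant.
#   OPCR - orientation patch count rotated: complexity as the number of
#          contiguous same-aspect face patches, averaged over sub-bin
#          rotations about z.
#   RFI  - relief index, ln(sqrt(3D area / projected area)).
#   PCV  - portion de ciel visible: per-vertex ambient occlusion, averaged.
#   SA   - 3D enamel surface area.
#   size - projected (occlusal outline) tooth area.

#' Options for Dirichlet normal energy
#'
#' @param outlier_energy_fraction fraction of faces, ranked by energy x area,
#'   removed from the top before summing (default 0.01, i.e. keep 99% of the
#'   energy-times-area ranking). No implicit fair smoothing is ever applied.
#' @param exclude_boundary_faces drop faces touching an open boundary before
#'   summation (default TRUE); boundary vertex normals are unreliable.
#' @export
dne_options <- function(outlier_energy_fraction = 0.01,
                        exclude_boundary_faces = TRUE) {
  stopifnot(outlier_energy_fraction >= 0, outlier_energy_fraction < 1)
  list(outlier_energy_fraction = outlier_energy_fraction,
       exclude_boundary_faces = exclude_boundary_faces)
}

#' Options for orientation patch count (rotated)
#'
#' @param n_bins number of azimuthal sectors (default 8, the classic
#'   compass-direction binning; sector 0 is centred on +x).
#' @param min_patch_size patches need at least this many edge-connected faces
#'   to count (default 3).
#' @param n_rotations rotations averaged for OPCR (default 8); the rotation
#'   step is `(360 / n_bins) / n_rotations` degrees, i.e. 5.625 for the
#'   defaults, so the rotations tile one bin exactly.
#' @param vertical_normal_epsilon faces whose normal has xy-magnitude at or
#'   below this are treated as vertical and excluded (azimuth undefined).
#' @export
opcr_options <- function(n_bins = 8L, min_patch_size = 3L, n_rotations = 8L,
                         vertical_normal_epsilon = 1e-6) {
  stopifnot(n_bins >= 2L, min_patch_size >= 1L, n_rotations >= 1L)
  list(n_bins = as.integer(n_bins), min_patch_size = as.integer(min_patch_size),
       n_rotations = as.integer(n_rotations),
       vertical_normal_epsilon = vertical_normal_epsilon)
}

#' Options for ambient occlusion (PCV)
#'
#' @param n_directions number of sky directions (default 256). Directions are
#'   a deterministic Fibonacci-spiral set on the upper unit hemisphere, so
#'   results are seed-free.
#' @param hemisphere_only sample only the upper hemisphere (the "visible sky"
#'   of an occlusal-up crown); default TRUE.
#' @param ray_offset rays start this far along the vertex normal (mm), to
#'   avoid self-intersection with incident faces.
#' @export
pcv_options <- function(n_directions = 256L, hemisphere_only = TRUE,
                        ray_offset = 1e-4) {
  stopifnot(n_directions >= 1L, ray_offset > 0)
  list(n_directions = as.integer(n_directions),
       hemisphere_only = hemisphere_only, ray_offset = ray_offset)
}

#' 3D surface area
#'
#' Sum of triangle areas (half-norm of the edge cross product), in mm^2.
#' @param mesh a [ct_mesh()].
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "ct_mesh"))
  sum(face_areas(mesh))
}

#' Projected tooth size (occlusal outline area)
#'
#' Area of the planar union of all triangles projected onto the xy-plane,
#' overlapping projections counted once, in mm^2. Computed by an exact-in-x
#' scanline integration (interval union per vertex-delimited slab, 2-point
#' Gauss in y). Optionally quantized to 0.0005 mm^2 steps to emulate tools
#' that report at that accuracy (off by default).
#'
#' @param mesh an occlusal-up [ct_mesh()].
#' @param quantize round the result to the nearest 0.0005 mm^2.
#' @return the projected area; 0 carries `attr(, "ct_degenerate") = TRUE`
#'   (a destroyed surface whose outline has vanished).
#' @export
projected_area <- function(mesh, quantize = FALSE) {
  stopifnot(inherits(mesh, "ct_mesh"))
  a <- .cpp_proj_union_area(mesh$vertices, mesh$faces)
  if (quantize) a <- round(a / 0.0005) * 0.0005
  if (a <= 0) {
    a <- 0
    attr(a, "ct_degenerate") <- TRUE
  }
  a
}

#' Relief index
#'
#' `RFI = ln(sqrt(surface_area / tooth_size))`: the log square-root ratio of
#' 3D surface area to projected outline area. Higher values mean relatively
#' taller crowns or cusps.
#'
#' @param surface_area 3D area, mm^2.
#' @param tooth_size projected outline area, mm^2.
#' @export
rfi <- function(surface_area, tooth_size) {
  if (!is.finite(tooth_size) || tooth_size <= 0)
    ct_stop("RFI undefined: projected tooth size is zero", "ct_undefined_metric_error")
  if (!is.finite(surface_area) || surface_area <= 0)
    ct_stop("RFI undefined: surface area is not positive", "ct_undefined_metric_error")
  log(sqrt(surface_area / tooth_size))
}

#' Dirichlet normal energy
#'
#' The Dirichlet energy of the normal map summed over the surface. Vertex
#' normals are area-weighted averages of incident face normals. For a face
#' with edge vectors `u, v` and vertex-normal differences `nu, nv`, the
#' energy density is `e = tr(G^-1 H)` with `G = [[u.u, u.v], [u.v, v.v]]` and
#' `H = [[nu.nu, nu.nv], [nu.nv, nv.nv]]`; DNE is the sum of `e * area` over
#' included faces after optionally dropping boundary-touching faces and the
#' top `outlier_energy_fraction` of faces ranked by `e * area` (ties broken
#' by face index). Scale invariant; 0 for a plane; converges to
#' `integral(k1^2 + k2^2) dA` (e.g. `4 * pi` for a hemisphere).
#'
#' @param mesh a [ct_mesh()].
#' @param opts a [dne_options()] list.
#' @return the energy, with attribute `n_skipped` counting degenerate faces.
#' @export
dne <- function(mesh, opts = dne_options()) {
  stopifnot(inherits(mesh, "ct_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  vn <- vertex_normals(mesh)

  p1 <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - p1
  w <- v[f[, 3L], , drop = FALSE] - p1
  n1 <- vn[f[, 1L], , drop = FALSE]
  nu <- vn[f[, 2L], , drop = FALSE] - n1
  nw <- vn[f[, 3L], , drop = FALSE] - n1

  g11 <- rowSums(u * u); g12 <- rowSums(u * w); g22 <- rowSums(w * w)
  h11 <- rowSums(nu * nu); h12 <- rowSums(nu * nw); h22 <- rowSums(nw * nw)
  det <- g11 * g22 - g12^2
  area <- 0.5 * sqrt(pmax(det, 0))
  ok <- is.finite(det) & det > 1e-24 * pmax(g11 * g22, 1e-300)
  e <- rep(NA_real_, nrow(f))
  e[ok] <- (g22[ok] * h11[ok] - 2 * g12[ok] * h12[ok] + g11[ok] * h22[ok]) / det[ok]
  n_skipped <- sum(!ok)

  include <- ok
  if (opts$exclude_boundary_faces) include <- include & !boundary_faces(mesh)
  ea <- e * area
  idx <- which(include)
  if (length(idx) && opts$outlier_energy_fraction > 0) {
    k <- floor(opts$outlier_energy_fraction * length(idx))
    if (k > 0) {
      ord <- idx[order(-ea[idx], idx)]  # highest energy x area first; tie: face index
      include[ord[seq_len(k)]] <- FALSE
    }
  }
  out <- sum(ea[include])
  attr(out, "n_skipped") <- n_skipped
  out
}

# Face azimuth bin assignment. Sector 0 is centred on +x; boundaries between
# sectors are assigned to the lower-index bin. Returns NA for excluded
# (vertical or downward) faces.
.opc_bins <- function(normals, opts, rotation_deg = 0) {
  nx <- normals[, 1L]; ny <- normals[, 2L]; nz <- normals[, 3L]
  xy <- sqrt(nx^2 + ny^2)
  included <- xy > opts$vertical_normal_epsilon & nz >= 0
  az <- (atan2(ny, nx) * 180 / pi + rotation_deg) %% 360
  sector <- 360 / opts$n_bins
  shifted <- (az + sector / 2) / sector
  bin <- floor(shifted)
  exact <- shifted == bin  # on a boundary: belongs to the lower bin
  bin[exact] <- bin[exact] - 1L
  bin <- bin %% opts$n_bins
  bin[!included] <- NA_integer_
  bin
}

# Edge-adjacent face pairs (m x 2 matrix), computed once per mesh.
.face_adjacency <- function(faces) {
  e <- all_face_edges(faces)
  fid <- rep(seq_len(nrow(faces)), 3L)
  key <- paste(e[, 1L], e[, 2L])
  ord <- order(key, fid)
  key <- key[ord]
  fid <- fid[ord]
  same <- key[-1L] == key[-length(key)]
  cbind(fid[c(same, FALSE)], fid[c(FALSE, same)])
}

#' Orientation patch count
#'
#' Faces are binned by the compass direction (azimuth) of their normal into
#' `n_bins` equal sectors; edge-connected runs of same-bin faces form
#' patches, and patches with at least `min_patch_size` faces are counted.
#' Vertical and downward-pointing faces are excluded. A horizontal plane
#' therefore scores 0.
#'
#' @param mesh an occlusal-up [ct_mesh()].
#' @param opts an [opcr_options()] list.
#' @param rotation_deg rotate the mesh about z by this many degrees before
#'   binning (used by [opcr()]).
#' @return integer patch count.
#' @export
opc <- function(mesh, opts = opcr_options(), rotation_deg = 0) {
  stopifnot(inherits(mesh, "ct_mesh"))
  bins <- .opc_bins(face_normals(mesh), opts, rotation_deg)
  adj <- .face_adjacency(mesh$faces)
  .count_patches(bins, adj, n_faces(mesh), opts$min_patch_size)
}

.count_patches <- function(bins, adj, m, min_patch_size) {
  inc <- !is.na(bins)
  if (!any(inc)) return(0L)
  same <- inc[adj[, 1L]] & inc[adj[, 2L]] & bins[adj[, 1L]] == bins[adj[, 2L]]
  same[is.na(same)] <- FALSE
  g <- igraph::make_graph(edges = as.vector(t(adj[same, , drop = FALSE])),
                          n = m, directed = FALSE)
  membership <- igraph::components(g)$membership
  sum(table(membership[inc]) >= min_patch_size)
}

#' Orientation patch count rotated
#'
#' The arithmetic mean of [opc()] over `n_rotations` rotations of the mesh
#' about z by multiples of `(360 / n_bins) / n_rotations` degrees, removing
#' the dependence of OPC on how the specimen happened to be oriented.
#'
#' @inheritParams opc
#' @return mean patch count (possibly fractional), with attribute
#'   `per_rotation` holding the individual OPC values.
#' @export
opcr <- function(mesh, opts = opcr_options()) {
  stopifnot(inherits(mesh, "ct_mesh"))
  step <- (360 / opts$n_bins) / opts$n_rotations
  normals <- face_normals(mesh)
  adj <- .face_adjacency(mesh$faces)
  vals <- vapply(seq_len(opts$n_rotations) - 1L, function(k) {
    bins <- .opc_bins(normals, opts, rotation_deg = k * step)
    as.double(.count_patches(bins, adj, n_faces(mesh), opts$min_patch_size))
  }, 0.0)
  out <- mean(vals)
  attr(out, "per_rotation") <- vals
  out
}

# Deterministic Fibonacci-spiral directions on the upper unit hemisphere.
.sky_directions <- function(n, hemisphere_only = TRUE) {
  i <- seq_len(n) - 0.5
  z <- if (hemisphere_only) i / n else 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-vertex ambient occlusion (portion de ciel visible)
#'
#' For every vertex, the fraction of a fixed set of sky directions along
#' which a ray from just above the vertex escapes without hitting the mesh.
#' Exposed cusps and crests approach 1; basin floors and fissures are lower.
#' Rays are cast from `vertex + ray_offset * vertex_normal` through a BVH.
#'
#' @param mesh an occlusal-up [ct_mesh()].
#' @param opts a [pcv_options()] list.
#' @return numeric vector of visibilities in `[0, 1]`, one per vertex.
#' @export
pcv_field <- function(mesh, opts = pcv_options()) {
  stopifnot(inherits(mesh, "ct_mesh"))
  dirs <- .sky_directions(opts$n_directions, opts$hemisphere_only)
  origins <- mesh$vertices + opts$ray_offset * vertex_normals(mesh)
  counts <- .cpp_visibility_counts(mesh$vertices, mesh$faces, origins, dirs)
  counts / opts$n_directions
}

#' Mean ambient occlusion over a surface
#'
#' Unweighted arithmetic mean of a per-vertex visibility field; on
#' near-uniform triangulations this tracks the area-weighted mean closely.
#'
#' @param field numeric vector from [pcv_field()].
#' @export
pcv_mean <- function(field) {
  if (!length(field)) ct_stop("empty PCV field", "ct_validation_error")
  mean(field)
}

#' Compute the full topographic metric set
#'
#' Runs all six measurements on a prepared surface and assembles a one-row
#' data frame (DNE, OPCR, RFI, mean PCV, surface area, tooth size, triangle
#' count, and resolution = count / area). Metrics that cannot be computed
#' (e.g. RFI on a destroyed surface whose outline area is 0) are recorded as
#' `NA` with a reason, never fabricated.
#'
#' @param mesh an occlusal-up [ct_mesh()].
#' @param metrics which metrics to compute; PCV is the expensive one and can
#'   be omitted.
#' @param dne_opts,opcr_opts,pcv_opts option lists.
#' @param quantize_size passed to [projected_area()].
#' @return a one-row data frame of class `ct_metric_set`; failed metrics are
#'   NA and `attr(, "reasons")` maps metric name to failure message.
#' @export
compute_metrics <- function(mesh,
                            metrics = c("dne", "opcr", "rfi", "pcv",
                                        "surface_area", "tooth_size"),
                            dne_opts = dne_options(),
                            opcr_opts = opcr_options(),
                            pcv_opts = pcv_options(),
                            quantize_size = FALSE) {
  stopifnot(inherits(mesh, "ct_mesh"))
  reasons <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      reasons[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  sa <- grab("surface_area", surface_area(mesh))
  size <- if ("tooth_size" %in% metrics || "rfi" %in% metrics)
    grab("tooth_size", as.double(projected_area(mesh, quantize = quantize_size)))
  else NA_real_
  out <- data.frame(
    dne = if ("dne" %in% metrics) grab("dne", as.double(dne(mesh, dne_opts))) else NA_real_,
    opcr = if ("opcr" %in% metrics) grab("opcr", as.double(opcr(mesh, opcr_opts))) else NA_real_,
    rfi = if ("rfi" %in% metrics) grab("rfi", rfi(sa, size)) else NA_real_,
    pcv_mean = if ("pcv" %in% metrics)
      grab("pcv", pcv_mean(pcv_field(mesh, pcv_opts))) else NA_real_,
    surface_area = sa,
    tooth_size = size,
    triangle_count = n_faces(mesh),
    resolution = if (is.finite(sa) && sa > 0) n_faces(mesh) / sa else NA_real_
  )
  class(out) <- c("ct_metric_set", "data.frame")
  attr(out, "reasons") <- reasons
  out
}
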