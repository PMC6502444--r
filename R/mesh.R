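#' Triangular crown mesh
#'
#' A minimal triangle-mesh container: an `n x 3` matrix of vertex coordinates
#' (assumed millimetres, occlusal surface toward +z once oriented) and an
#' `m x 3` integer matrix of 1-based vertex indices. Optional named per-vertex
#' scalar fields (e.g. ambient-occlusion values in `[0, 1]`) ride along in
#' `fields` and survive PLY round-trips.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param fields optional named list of per-vertex numeric vectors.
#' @return An object of class `ct_mesh`.
#' @export
ct_mesh <- function(vertices, faces, fields = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) faces <- matrix(integer(), 0L, 3L)
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  fields <- fields %||% list()
  if (length(fields)) {
    bad <- vapply(fields, function(f) length(f) != nrow(vertices), FALSE)
    if (any(bad)) stop("per-vertex fields must have one value per vertex")
  }
  structure(list(vertices = vertices, faces = faces, fields = fields),
            class = "ct_mesh")
}

#' @export
print.ct_mesh <- function(x, ...) {
  cat(sprintf("<ct_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (length(x$fields))
                paste0(", fields: ", paste(names(x$fields), collapse = ", "))
              else ""))
  invisible(x)
}

n_faces <- function(mesh) nrow(mesh$faces)
n_vertices <- function(mesh) nrow(mesh$vertices)

# Unnormalized per-face cross products (2 * area * unit normal).
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - a
  w <- v[f[, 3L], , drop = FALSE] - a
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

face_areas <- function(mesh) 0.5 * sqrt(rowSums(face_cross(mesh)^2))

face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

# Area-weighted vertex normals: incident unnormalized cross products summed,
# then unit-normalized (summing the raw cross product is the area weighting).
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)
  f <- mesh$faces
  nv <- n_vertices(mesh)
  acc <- matrix(0, nv, 3L)
  for (k in 1:3) {
    acc[, 1L] <- acc[, 1L] + unname(tapply_sum(cr[, 1L], f[, k], nv))
    acc[, 2L] <- acc[, 2L] + unname(tapply_sum(cr[, 2L], f[, k], nv))
    acc[, 3L] <- acc[, 3L] + unname(tapply_sum(cr[, 3L], f[, k], nv))
  }
  nrm <- sqrt(rowSums(acc^2))
  nrm[nrm == 0] <- 1
  acc / nrm
}

# Sum `x` into `n` bins indexed by `idx` (1-based); dense result.
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Undirected edges, one row per face-edge occurrence (3 * m rows).
all_face_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

# Edge occurrence counts; boundary edges occur exactly once.
edge_table <- function(faces) {
  e <- all_face_edges(faces)
  key <- paste(e[, 1L], e[, 2L])
  list(edges = e, key = key, count = table(key))
}

boundary_vertices <- function(mesh) {
  et <- edge_table(mesh$faces)
  once <- names(et$count)[et$count == 1L]
  if (!length(once)) return(integer())
  m <- do.call(rbind, strsplit(once, " ", fixed = TRUE))
  sort(unique(as.integer(m)))
}

# Faces touching an open boundary (any vertex on a boundary edge).
boundary_faces <- function(mesh) {
  bv <- boundary_vertices(mesh)
  if (!length(bv)) return(logical(n_faces(mesh)))
  rowSums(matrix(mesh$faces %in% bv, ncol = 3L)) > 0
}

#' Clean and audit a mesh
#'
#' Welds vertices that fall in the same cell of a `weld_tolerance`-sized grid,
#' drops zero-area, repeated-vertex and duplicate faces, removes unreferenced
#' vertices, and reports the cleaned mesh's bookkeeping. Surviving geometry is
#' never altered beyond the welding itself (kept vertices retain their original
#' coordinates). Idempotent: validating a validated mesh changes nothing.
#'
#' @param mesh a [ct_mesh()].
#' @param weld_tolerance welding distance in mm; default `1e-6`, far below
#'   the 10--100 micrometre resolution of the scanners these meshes come from.
#' @return list with elements `mesh` (cleaned) and `report`
#'   (class `ct_mesh_report`: vertex/face/degenerate/boundary-edge counts,
#'   Euler characteristic V - E + F, and the bounding box).
#' @export
validate_mesh <- function(mesh, weld_tolerance = 1e-6) {
  stopifnot(inherits(mesh, "ct_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) ct_stop("mesh has non-finite vertex coordinates", "ct_validation_error")
  if (nrow(f) && (min(f) < 1L || max(f) > nrow(v)))
    ct_stop("face index out of range", "ct_validation_error")

  # Weld: snap to a tolerance grid, keep the first vertex in each cell.
  key <- paste(round(v[, 1L] / weld_tolerance),
               round(v[, 2L] / weld_tolerance),
               round(v[, 3L] / weld_tolerance))
  first <- match(key, key)
  remap <- match(first, unique(first))
  vkeep <- v[unique(first), , drop = FALSE]
  fields <- lapply(mesh$fields, function(x) x[unique(first)])
  f2 <- matrix(remap[f], ncol = 3L)

  degen <- f2[, 1L] == f2[, 2L] | f2[, 2L] == f2[, 3L] | f2[, 1L] == f2[, 3L]
  f2 <- f2[!degen, , drop = FALSE]
  n_degenerate <- sum(degen)

  if (nrow(f2)) {
    m0 <- ct_mesh(vkeep, f2)
    zero <- face_areas(m0) <= 1e-12
    n_degenerate <- n_degenerate + sum(zero)
    f2 <- f2[!zero, , drop = FALSE]
  }
  if (nrow(f2)) {
    skey <- apply(f2, 1L, function(r) paste(sort(r), collapse = " "))
    dup <- duplicated(skey)
    n_degenerate <- n_degenerate + sum(dup)
    f2 <- f2[!dup, , drop = FALSE]
  }
  if (!nrow(f2))
    ct_stop("mesh is empty after cleaning (all faces degenerate)", "ct_degenerate_error")

  used <- sort(unique(as.vector(f2)))
  f3 <- matrix(match(f2, used), ncol = 3L)
  v3 <- vkeep[used, , drop = FALSE]
  fields <- lapply(fields, function(x) x[used])
  out <- ct_mesh(v3, f3, fields)

  et <- edge_table(out$faces)
  n_edges <- length(et$count)
  report <- structure(list(
    n_vertices = nrow(v3),
    n_faces = nrow(f3),
    n_degenerate = n_degenerate,
    n_boundary_edges = sum(et$count == 1L),
    euler_characteristic = nrow(v3) - n_edges + nrow(f3),
    bounding_box = c(xmin = min(v3[, 1L]), ymin = min(v3[, 2L]), zmin = min(v3[, 3L]),
                     xmax = max(v3[, 1L]), ymax = max(v3[, 2L]), zmax = max(v3[, 3L]))
  ), class = "ct_mesh_report")
  list(mesh = out, report = report)
}

#' @export
print.ct_mesh_report <- function(x, ...) {
  cat(sprintf(paste0("<mesh report: V=%d F=%d degenerate=%d boundary edges=%d ",
                     "Euler=%d>\n"),
              x$n_vertices, x$n_faces, x$n_degenerate,
              x$n_boundary_edges, x$euler_characteristic))
  invisible(x)
}

#' Enforce the occlusal-up convention
#'
#' Prepared crowns are analysed with the occlusal (chewing) surface toward +z.
#' With `flip = TRUE` the mesh is rotated 180 degrees about the x-axis
#' (y and z negated), the operation used to right an upside-down scan.
#' With `flip = FALSE` the orientation is asserted: the mean unit face normal
#' must have a positive z-component.
#'
#' @param mesh a [ct_mesh()].
#' @param flip apply the 180-degree rotation before checking.
#' @return The (possibly rotated) mesh, guaranteed occlusal-up.
#' @export
orient_occlusal <- function(mesh, flip = FALSE) {
  stopifnot(inherits(mesh, "ct_mesh"))
  if (flip) {
    mesh$vertices[, 2L] <- -mesh$vertices[, 2L]
    mesh$vertices[, 3L] <- -mesh$vertices[, 3L]
  }
  mz <- mean(face_normals(mesh)[, 3L])
  if (mz <= 0)
    ct_stop("mean face normal does not point in +z; occlusal surface is not up",
            "ct_orientation_error")
  mesh
}
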