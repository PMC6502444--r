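# Surface-preparation operators. The canonical pipeline order is
# crop -> decimate -> smooth: smoothing must come last because decimation
# leaves an irregular surface that would otherwise stay rough.

#' Canonical resampling ladders
#'
#' The two standard level ladders for resampling studies: absolute triangle
#' counts, and resolutions in triangles per square millimetre of (cropped)
#' surface area.
#' @param mode `"count"` or `"resolution"`.
#' @return numeric vector of ladder levels.
#' @export
resample_ladder <- function(mode = c("count", "resolution")) {
  mode <- match.arg(mode)
  if (mode == "count") c(100, 200, 500, 1000, 2000, 5000, 10000, 20000, 50000, 100000)
  else c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000)
}

#' Decimate a mesh to a target triangle count
#'
#' Quadric edge-collapse simplification with boundary preservation. Always
#' applied to the original mesh at hand, never chained (a study ladder must
#' decimate each level from the unaltered input, not re-simplify a previous
#' level). Deterministic: ties in the collapse queue break on the lowest
#' vertex-index pair.
#'
#' @param mesh a [ct_mesh()].
#' @param n target triangle count (`>= 4`). The result has between `n - 2`
#'   and `n` faces (a collapse removes one or two faces at a time).
#' @return the decimated mesh; if `n` is at or above the current face count
#'   the input is returned unchanged with a warning. Per-vertex fields are
#'   dropped (collapsed vertices have no well-defined field value).
#' @export
decimate_to_count <- function(mesh, n) {
  stopifnot(inherits(mesh, "ct_mesh"))
  n <- as.integer(n)
  if (n < 4L) ct_stop("target triangle count must be at least 4", "ct_degenerate_error")
  if (n >= n_faces(mesh)) {
    if (n > n_faces(mesh))
      warning(sprintf("mesh has %d faces; cannot simplify up to %d, returning unchanged",
                      n_faces(mesh), n))
    return(mesh)
  }
  res <- .cpp_quadric_decimate(mesh$vertices, mesh$faces, n)
  out <- ct_mesh(res$vertices, res$faces)
  if (n_faces(out) > n)
    warning(sprintf("decimation stalled at %d faces (target %d)", n_faces(out), n))
  out
}

#' Decimate a mesh to a target resolution
#'
#' Resolution is triangles per square millimetre of surface area, measured on
#' the input (already-cropped) mesh: `target_count = round(r * SA)`, then the
#' mesh is simplified exactly as [decimate_to_count()].
#'
#' @param mesh a [ct_mesh()] (cropped first, per the standard pipeline order).
#' @param r target resolution in triangles/mm^2.
#' @return list with `mesh` and the derived `target_count`.
#' @export
decimate_to_resolution <- function(mesh, r) {
  stopifnot(inherits(mesh, "ct_mesh"), r > 0)
  target <- as.integer(round(r * surface_area(mesh)))
  if (target < 4L)
    ct_stop(sprintf("resolution %g triangles/mm^2 gives a target of %d triangles (< 4)",
                    r, target), "ct_degenerate_error")
  list(mesh = decimate_to_count(mesh, target), target_count = target)
}

#' Iterative Laplacian smoothing
#'
#' Each iteration moves every vertex by `lambda_step` times the vector toward
#' the unweighted centroid of its edge-connected neighbours. Vertices on an
#' open boundary average only over their boundary neighbours, so a cropped rim
#' cannot migrate inward. Connectivity is unchanged. The defaults
#' (`lambda_step = 0.6`, `iterations = 100`) are the settings conventionally
#' used when preparing crowns for topographic analysis. A positive step
#' systematically shrinks surface area on noisy surfaces, which is the
#' behaviour under study; no shrink compensation is applied.
#'
#' @param mesh a [ct_mesh()].
#' @param lambda_step step size in `(0, 1]` (0 is allowed and is the identity).
#' @param iterations number of smoothing passes.
#' @return the smoothed mesh. If smoothing collapses the surface to (near)
#'   zero projected extent, the result carries `attr(, "ct_destroyed") = TRUE`
#'   and a warning is raised, mirroring the destroyed-surface failure mode of
#'   heavily simplified crowns.
#' @export
smooth_mesh <- function(mesh, lambda_step = 0.6, iterations = 100L) {
  stopifnot(inherits(mesh, "ct_mesh"),
            lambda_step >= 0, lambda_step <= 1, iterations >= 0)
  if (lambda_step == 0 || iterations == 0L) return(mesh)
  v <- mesh$vertices
  nv <- nrow(v)

  et <- edge_table(mesh$faces)
  e <- unique(et$edges)
  bkey <- names(et$count)[et$count == 1L]
  is_bedge <- paste(e[, 1L], e[, 2L]) %in% bkey
  bverts <- unique(as.vector(e[is_bedge, , drop = FALSE]))

  from <- c(e[, 1L], e[, 2L])
  to <- c(e[, 2L], e[, 1L])
  interior_row <- !(from %in% bverts)
  bfrom <- c(e[is_bedge, 1L], e[is_bedge, 2L])
  bto <- c(e[is_bedge, 2L], e[is_bedge, 1L])
  rows <- c(from[interior_row], bfrom)
  cols <- c(to[interior_row], bto)

  A <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  fixed <- deg == 0
  deg[fixed] <- 1
  A <- Matrix::Diagonal(x = 1 / deg) %*% A
  # row operator: (1 - lambda) I + lambda A; fixed vertices stay put
  lam <- ifelse(fixed, 0, lambda_step)
  M <- Matrix::Diagonal(x = 1 - lam) + Matrix::Diagonal(x = lam) %*% A

  for (i in seq_len(iterations)) v <- as.matrix(M %*% v)
  out <- ct_mesh(v, mesh$faces, mesh$fields)
  bb <- apply(out$vertices, 2L, range)
  if (prod(bb[2L, 1:2] - bb[1L, 1:2]) < 1e-12) {
    warning("smoothing collapsed the surface to zero projected extent")
    attr(out, "ct_destroyed") <- TRUE
  }
  out
}

#' Crop a crown at a horizontal basin plane (basin cut-off)
#'
#' Retains the part of the surface at or above `z_plane`. Faces crossing the
#' plane are split so the cut boundary lies exactly at `z = z_plane`; the
#' result has an open boundary along the cut.
#'
#' @param mesh an occlusal-up [ct_mesh()].
#' @param z_plane cut height in mm.
#' @return the cropped mesh. `z_plane` below the mesh returns the input
#'   unchanged; `z_plane` above the mesh is a degenerate-input error.
#' @export
crop_bco <- function(mesh, z_plane) {
  stopifnot(inherits(mesh, "ct_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  z <- v[, 3L]
  if (z_plane > max(z))
    ct_stop("cropping plane lies above the entire mesh", "ct_degenerate_error")
  if (z_plane <= min(z)) return(mesh)

  above <- z >= z_plane
  nab <- matrix(above[f], ncol = 3L)
  cnt <- rowSums(nab)

  keep <- f[cnt == 3L, , drop = FALSE]
  cross_idx <- which(cnt == 1L | cnt == 2L)

  newv <- list()
  fields <- mesh$fields
  newfields <- lapply(fields, function(x) list())
  cache <- new.env(parent = emptyenv())
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    a <- min(i, j); b <- max(i, j)           # deterministic interpolation order
    t <- (z_plane - v[a, 3L]) / (v[b, 3L] - v[a, 3L])
    if (t <= 0) { assign(key, a, envir = cache); return(a) }  # endpoint on plane
    if (t >= 1) { assign(key, b, envir = cache); return(b) }
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    p[3L] <- z_plane
    id <- nrow(v) + length(newv) + 1L
    newv[[length(newv) + 1L]] <<- p
    for (nm in names(fields))
      newfields[[nm]][[length(newfields[[nm]]) + 1L]] <<-
        fields[[nm]][a] + t * (fields[[nm]][b] - fields[[nm]][a])
    assign(key, id, envir = cache)
    id
  }

  extra <- vector("list", length(cross_idx))
  for (q in seq_along(cross_idx)) {
    fi <- cross_idx[q]
    tri <- f[fi, ]
    ab <- nab[fi, ]
    if (sum(ab) == 1L) {
      r <- which(ab)                          # rotate so vertex 1 is above
      ord <- ((r - 1L) + 0:2) %% 3L + 1L
      tri <- tri[ord]
      i12 <- cut_point(tri[1L], tri[2L])
      i31 <- cut_point(tri[3L], tri[1L])
      extra[[q]] <- matrix(c(tri[1L], i12, i31), 1L, 3L)
    } else {
      r <- which(!ab)                         # rotate so vertex 3 is below
      ord <- (r + 0:2) %% 3L + 1L
      tri <- tri[ord]
      i23 <- cut_point(tri[2L], tri[3L])
      i31 <- cut_point(tri[3L], tri[1L])
      extra[[q]] <- rbind(c(tri[1L], tri[2L], i23),
                          c(tri[1L], i23, i31))
    }
  }

  vall <- rbind(v, do.call(rbind, newv))
  fall <- rbind(keep, do.call(rbind, extra))
  # cut points that coincided with an endpoint can collapse a split triangle
  ok <- fall[, 1L] != fall[, 2L] & fall[, 2L] != fall[, 3L] & fall[, 1L] != fall[, 3L]
  fall <- fall[ok, , drop = FALSE]
  fields_all <- if (length(fields))
    Map(function(old, nw) c(old, unlist(nw)), fields, newfields)
  else list()

  used <- sort(unique(as.vector(fall)))
  out <- ct_mesh(vall[used, , drop = FALSE],
                 matrix(match(fall, used), ncol = 3L),
                 lapply(fields_all, function(x) x[used]))
  if (!n_faces(out))
    ct_stop("nothing left above the cropping plane", "ct_degenerate_error")
  out
}

#' Estimate the basin cut-off plane height
#'
#' A heuristic stand-in for the manual landmark "lowest point of the central
#' occlusal basin": returns the minimum z among vertices whose xy-projection
#' falls inside the projected convex hull shrunk toward its centroid by
#' `margin_fraction`. Shrinking excludes the crown's outer walls so that the
#' minimum is taken over the occlusal basin rather than the cervical rim.
#' Batch studies may instead supply per-specimen plane heights directly to
#' [crop_bco()].
#'
#' @param mesh an occlusal-up [ct_mesh()].
#' @param margin_fraction fraction in `[0, 1)` by which the hull is shrunk
#'   (default 0.25); 0 keeps the full outline.
#' @return the estimated plane height z in mm.
#' @export
estimate_basin_plane <- function(mesh, margin_fraction = 0.25) {
  stopifnot(inherits(mesh, "ct_mesh"),
            margin_fraction >= 0, margin_fraction < 1)
  v <- mesh$vertices
  hull <- grDevices::chull(v[, 1L], v[, 2L])
  hx <- v[hull, 1L]
  hy <- v[hull, 2L]
  cx <- mean(hx)
  cy <- mean(hy)
  s <- 1 - margin_fraction
  hx <- cx + s * (hx - cx)
  hy <- cy + s * (hy - cy)

  # Point-in-convex-polygon with tolerance, robust to hull winding direction.
  n <- length(hx)
  nxt <- c(2:n, 1L)
  eps <- 1e-9 * max(diff(range(v[, 1L])), diff(range(v[, 2L])), 1e-12)
  ccw <- sum(hx * hy[nxt] - hx[nxt] * hy) > 0
  inside <- rep(TRUE, nrow(v))
  for (k in seq_len(n)) {
    ex <- hx[nxt[k]] - hx[k]
    ey <- hy[nxt[k]] - hy[k]
    cr <- ex * (v[, 2L] - hy[k]) - ey * (v[, 1L] - hx[k])
    inside <- inside & if (ccw) cr >= -eps else cr <= eps
  }
  if (!any(inside))
    ct_stop("no vertices inside the shrunk outline; cannot estimate basin plane",
            "ct_estimation_error")
  min(v[inside, 3L])
}
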