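# Independent oracles and small fixtures, kept deliberately naive so they
# share no code path with the implementations they check.

# --- brute-force flood-fill OPC ---------------------------------------------
# Adjacency by O(F^2) shared-vertex-pair comparison; patches by BFS.
oracle_opc_flood <- function(mesh, opts = opcr_options(), rotation_deg = 0) {
  v <- mesh$vertices
  f <- mesh$faces
  m <- nrow(f)
  # face normals, written out longhand
  n <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    u <- b - a; w <- c - a
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    len <- sqrt(sum(cr^2))
    if (len > 0) n[i, ] <- cr / len
  }
  xy <- sqrt(n[, 1]^2 + n[, 2]^2)
  included <- xy > opts$vertical_normal_epsilon & n[, 3] >= 0
  az <- (atan2(n[, 2], n[, 1]) * 180 / pi + rotation_deg) %% 360
  sector <- 360 / opts$n_bins
  shifted <- (az + sector / 2) / sector
  bin <- floor(shifted)
  bin[shifted == bin] <- bin[shifted == bin] - 1
  bin <- bin %% opts$n_bins
  bin[!included] <- NA

  shares_edge <- function(i, j) length(intersect(f[i, ], f[j, ])) >= 2
  visited <- rep(FALSE, m)
  patches <- 0L
  for (s in seq_len(m)) {
    if (visited[s] || is.na(bin[s])) next
    queue <- s
    visited[s] <- TRUE
    comp <- integer()
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, cur)
      for (j in seq_len(m)) {
        if (!visited[j] && !is.na(bin[j]) && bin[j] == bin[cur] &&
            shares_edge(cur, j)) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    if (length(comp) >= opts$min_patch_size) patches <- patches + 1L
  }
  patches
}

# --- naive any-hit ray casting (vectorized Moller-Trumbore over faces) ------
oracle_ray_hits_any <- function(V, Fm, o, d) {
  a <- V[Fm[, 1], , drop = FALSE]
  e1 <- V[Fm[, 2], , drop = FALSE] - a
  e2 <- V[Fm[, 3], , drop = FALSE] - a
  p <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-14
  s <- cbind(o[1] - a[, 1], o[2] - a[, 2], o[3] - a[, 3])
  u <- rowSums(s * p) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (d[1] * q[, 1] + d[2] * q[, 2] + d[3] * q[, 3]) / det
  th <- rowSums(e2 * q) / det
  any(ok & u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & th > 1e-9, na.rm = TRUE)
}

oracle_pcv <- function(mesh, vertex_ids, dirs, ray_offset = 1e-4) {
  vn <- crowntopo:::vertex_normals(mesh)
  out <- numeric(length(vertex_ids))
  for (k in seq_along(vertex_ids)) {
    vi <- vertex_ids[k]
    o <- mesh$vertices[vi, ] + ray_offset * vn[vi, ]
    vis <- 0L
    for (j in seq_len(nrow(dirs)))
      if (!oracle_ray_hits_any(mesh$vertices, mesh$faces, o, dirs[j, ]))
        vis <- vis + 1L
    out[k] <- vis / nrow(dirs)
  }
  out
}

# --- permutation references for the group tests -----------------------------
manual_f_stat <- function(y, g) {
  g <- factor(g)
  gm <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  ssb <- sum(n * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  k <- nlevels(g)
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}

perm_anova_p <- function(y, g, nperm = 4000) {
  obs <- manual_f_stat(y, g)
  hits <- 0L
  for (i in seq_len(nperm))
    if (manual_f_stat(sample(y), g) >= obs) hits <- hits + 1L
  hits / nperm
}

# Single-step max-|standardized difference| permutation analogue of Tukey HSD.
perm_tukey_p <- function(y, g, nperm = 4000) {
  g <- factor(g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  stat <- function(y) {
    gm <- tapply(y, g, mean)
    n <- tapply(y, g, length)
    s2 <- sum((y - gm[g])^2) / (length(y) - nlevels(g))
    vapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      abs(gm[a] - gm[b]) / sqrt(s2 / 2 * (1 / n[a] + 1 / n[b]))
    }, 0.0)
  }
  obs <- stat(y)
  exceed <- numeric(length(obs))
  for (i in seq_len(nperm)) {
    mx <- max(stat(sample(y)))
    exceed <- exceed + (mx >= obs)
  }
  p <- exceed / nperm
  names(p) <- paste(pairs[2, ], pairs[1, ], sep = "-")
  p
}

# --- small fixtures ---------------------------------------------------------
make_tetra <- function() {
  ct_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.5, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(3, 1, 4)))
}

# Open-top square well: floor [-half, half]^2 at z = 0, walls up to `height`.
make_well <- function(half = 1, height = 2, n = 6L) {
  fl <- make_plane(2 * half, 2 * half, 2L * n * n)
  fl$vertices[, 1] <- fl$vertices[, 1] - half
  fl$vertices[, 2] <- fl$vertices[, 2] - half
  wall_grid <- function(fix_axis, fix_val) {
    s <- seq(-half, half, length.out = n + 1L)
    z <- seq(0, height, length.out = n + 1L)
    pts <- if (fix_axis == 1L)
      cbind(fix_val, rep(s, times = n + 1L), rep(z, each = n + 1L))
    else
      cbind(rep(s, times = n + 1L), fix_val, rep(z, each = n + 1L))
    id <- function(i, j) (j - 1L) * (n + 1L) + i
    i <- rep(seq_len(n), times = n)
    j <- rep(seq_len(n), each = n)
    ct_mesh(pts, rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                       cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))))
  }
  parts <- list(fl, wall_grid(1L, -half), wall_grid(1L, half),
                wall_grid(2L, -half), wall_grid(2L, half))
  v <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  off <- cumsum(c(0L, vapply(parts, function(p) nrow(p$vertices), 0L)))
  f <- do.call(rbind, Map(function(p, o) p$faces + o, parts, off[-length(off)]))
  ct_mesh(v, f)
}

# Random small bumpy height-field mesh (for oracle-equivalence sweeps).
random_bumpy_mesh <- function(seed, n = 6L) {
  set.seed(seed)
  g <- seq(0, 1, length.out = n + 1L)
  v <- cbind(rep(g, times = n + 1L), rep(g, each = n + 1L),
             stats::rnorm((n + 1L)^2, sd = 0.15))
  id <- function(i, j) (j - 1L) * (n + 1L) + i
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  ct_mesh(v, rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                   cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))))
}

rotate_z <- function(mesh, deg) {
  th <- deg * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mesh$vertices <- mesh$vertices %*% t(R)
  mesh
}
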