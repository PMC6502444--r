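# PLY input/output. Only the two dialects the dental-topography toolchain
# exchanges are supported: "format ascii 1.0" and "format binary_little_endian
# 1.0". Big-endian files are rejected with a clear message. Quad (or larger)
# faces are fan-triangulated at their first vertex. Extra per-vertex scalar
# properties (e.g. a PCV field) are read into `mesh$fields`; normals in the
# file are ignored because the package always recomputes them from geometry.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw, off, type, path) {
  sz <- .ply_type_size[[type]]
  if (off + sz - 1L > length(raw))
    ct_stop(sprintf("truncated PLY payload in '%s' at byte %d", path, off),
            "ct_format_error")
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  val <- readBin(raw[off:(off + sz - 1L)], what = what, size = sz,
                 n = 1L, endian = "little", signed = if (sz < 4L) signed else TRUE)
  list(value = as.double(val), off = off + sz)
}

#' Read a PLY surface mesh
#'
#' @param path path to an ASCII or binary little-endian PLY file with x/y/z
#'   vertex properties and a face element carrying a vertex-index list.
#' @return a [ct_mesh()]; quad faces are fan-split into triangles, coordinates
#'   are kept in the file's units (assumed mm).
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) ct_stop(sprintf("no such file: '%s'", path), "ct_io_error")
  con <- file(path, "rb")
  on.exit(close(con))

  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line))
      ct_stop(sprintf("'%s': header ended before end_header", path), "ct_format_error")
    line <- sub("\r$", "", line)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 1000L)
      ct_stop(sprintf("'%s': header too long; not a PLY file?", path), "ct_format_error")
  }
  if (header[1L] != "ply")
    ct_stop(sprintf("'%s' line 1: missing 'ply' magic", path), "ct_format_error")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L)
    ct_stop(sprintf("'%s': missing format line", path), "ct_format_error")
  fmt <- strsplit(fmt_line, "\\s+")[[1L]][2L]
  if (fmt == "binary_big_endian")
    ct_stop(sprintf("'%s': big-endian PLY is not supported; convert to ascii or binary_little_endian", path),
            "ct_format_error")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    ct_stop(sprintf("'%s': unknown PLY format '%s'", path, fmt), "ct_format_error")

  # Parse element/property declarations, in file order.
  elements <- list()
  cur <- NULL
  for (i in seq_along(header)) {
    tok <- strsplit(header[i], "\\s+")[[1L]]
    if (!length(tok)) next
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props[[tok[5L]]] <- list(list = TRUE, count_type = tok[3L], value_type = tok[4L])
      } else {
        cur$props[[tok[3L]]] <- list(list = FALSE, type = tok[2L])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    ct_stop(sprintf("'%s': PLY must declare vertex and face elements", path), "ct_format_error")
  vp <- elements$vertex$props
  if (!all(c("x", "y", "z") %in% names(vp)))
    ct_stop(sprintf("'%s': vertex element lacks x/y/z properties", path), "ct_format_error")
  if (any(vapply(vp, function(p) isTRUE(p$list), FALSE)))
    ct_stop(sprintf("'%s': list-typed vertex properties are not supported", path), "ct_format_error")

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- sub("\r$", "", body)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    take <- function(n, what) {
      if (pos + n > length(body))
        ct_stop(sprintf("'%s': truncated payload; expected %d more %s line(s) after line %d",
                        path, pos + n - length(body), what,
                        length(header) + length(body)), "ct_format_error")
      out <- body[(pos + 1L):(pos + n)]
      pos <<- pos + n
      out
    }
    verts <- NULL
    faces_raw <- NULL
    fields <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        lines <- take(el$count, "vertex")
        vals <- scan(text = lines, quiet = TRUE)
        np <- length(el$props)
        if (length(vals) != el$count * np)
          ct_stop(sprintf("'%s': vertex payload malformed", path), "ct_format_error")
        m <- matrix(vals, ncol = np, byrow = TRUE)
        colnames(m) <- names(el$props)
        verts <- m[, c("x", "y", "z"), drop = FALSE]
        extra <- setdiff(names(el$props), c("x", "y", "z", "nx", "ny", "nz"))
        for (nm in extra) fields[[nm]] <- m[, nm]
      } else if (el$name == "face") {
        lines <- take(el$count, "face")
        faces_raw <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
      } else {
        take(el$count, el$name)  # skip unknown elements line-wise
      }
    }
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    off <- 1L
    verts <- NULL
    faces_raw <- NULL
    fields <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        types <- vapply(el$props, function(p) p$type, "")
        np <- length(types)
        if (length(unique(types)) == 1L) {
          sz <- .ply_type_size[[types[1L]]]
          need <- el$count * np * sz
          if (off + need - 1L > length(raw))
            ct_stop(sprintf("truncated PLY payload in '%s' at byte %d (vertex data)", path, off),
                    "ct_format_error")
          what <- if (types[1L] %in% c("float", "float32", "double", "float64")) "double" else "integer"
          vals <- readBin(raw[off:(off + need - 1L)], what, n = el$count * np,
                          size = sz, endian = "little",
                          signed = if (sz < 4L) !grepl("^u", types[1L]) else TRUE)
          off <- off + need
          m <- matrix(as.double(vals), ncol = np, byrow = TRUE)
        } else {
          m <- matrix(0, el$count, np)
          for (r in seq_len(el$count)) for (c in seq_len(np)) {
            sc <- .ply_read_scalar(raw, off, types[c], path)
            m[r, c] <- sc$value
            off <- sc$off
          }
        }
        colnames(m) <- names(el$props)
        verts <- m[, c("x", "y", "z"), drop = FALSE]
        extra <- setdiff(names(el$props), c("x", "y", "z", "nx", "ny", "nz"))
        for (nm in extra) fields[[nm]] <- m[, nm]
      } else if (el$name == "face") {
        lp <- el$props[[1L]]
        if (length(el$props) != 1L || !isTRUE(lp$list))
          ct_stop(sprintf("'%s': face element must carry a single vertex-index list", path),
                  "ct_format_error")
        faces_raw <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          sc <- .ply_read_scalar(raw, off, lp$count_type, path)
          k <- as.integer(sc$value)
          off <- sc$off
          idx <- integer(k)
          for (j in seq_len(k)) {
            sc <- .ply_read_scalar(raw, off, lp$value_type, path)
            idx[j] <- as.integer(sc$value)
            off <- sc$off
          }
          faces_raw[[r]] <- c(k, idx)
        }
      } else {
        if (any(vapply(el$props, function(p) isTRUE(p$list), FALSE)))
          ct_stop(sprintf("'%s': cannot skip binary element '%s' with list properties",
                          path, el$name), "ct_format_error")
        stride <- sum(vapply(el$props, function(p) .ply_type_size[[p$type]], 0L))
        off <- off + el$count * stride
      }
    }
  }

  # Fan-triangulate: (v1, v_i, v_i+1) for i = 2..k-1.
  tris <- vector("list", length(faces_raw))
  for (r in seq_along(faces_raw)) {
    rec <- faces_raw[[r]]
    k <- rec[1L]
    if (is.na(k) || k < 3L || length(rec) != k + 1L)
      ct_stop(sprintf("'%s': face %d is malformed or not triangulatable", path, r),
              "ct_format_error")
    idx <- rec[-1L] + 1L  # PLY is 0-based
    tris[[r]] <- cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
  }
  faces <- do.call(rbind, tris)
  if (any(faces < 1L) || any(faces > nrow(verts)))
    ct_stop(sprintf("'%s': face references a vertex outside the declared range", path),
            "ct_format_error")
  ct_mesh(verts, faces, fields)
}

#' Write a PLY surface mesh
#'
#' Vertex coordinates (and any per-vertex fields) are written as doubles, so
#' the binary dialect round-trips bit-exactly and is byte-stable for identical
#' input; the ASCII dialect prints 17 significant digits.
#'
#' @param mesh a [ct_mesh()]; must contain only finite coordinates.
#' @param path output path.
#' @param dialect `"binary_le"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, dialect = c("binary_le", "ascii")) {
  stopifnot(inherits(mesh, "ct_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v)))
    ct_stop("mesh has non-finite vertex coordinates; refusing to write", "ct_validation_error")
  if (nrow(f) && (min(f) < 1L || max(f) > nrow(v)))
    ct_stop("face index out of range; refusing to write", "ct_validation_error")

  fields <- mesh$fields
  fmt <- if (dialect == "ascii") "ascii" else "binary_little_endian"
  hdr <- c("ply",
           sprintf("format %s 1.0", fmt),
           "comment written by crowntopo",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (length(fields)) sprintf("property double %s", names(fields)),
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")

  vmat <- cbind(v, do.call(cbind, c(list(NULL), unname(fields))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (dialect == "ascii") {
    vl <- apply(vmat, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(vl, con, sep = "\n")
    fl <- paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
    writeLines(fl, con, sep = "\n")
  } else {
    writeBin(as.vector(t(vmat)), con, size = 8L, endian = "little")
    if (nrow(f)) {
      ints <- writeBin(as.integer(t(f) - 1L), raw(), size = 4L, endian = "little")
      im <- matrix(ints, nrow = 12L)
      payload <- rbind(matrix(as.raw(3L), 1L, nrow(f)), im)
      writeBin(as.vector(payload), con)
    }
  }
  invisible(path)
}
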