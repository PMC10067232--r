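#' Read an STL file (binary or ASCII)
#'
#' Coordinates are interpreted as millimetres. Vertices are deduplicated by
#' exact coordinate equality (use [weld()] for tolerance-based merging).
#'
#' @param path STL file path.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 84)
  # Binary files may also start with "solid", so binary-ness is decided by
  # consistency of the facet count at offset 80 with the file size.
  is_binary <- FALSE
  nfac <- 0L
  if (length(head) == 84) {
    nfac <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
    is_binary <- !is.na(nfac) && nfac >= 0 && size == 84 + 50 * as.numeric(nfac)
  }
  if (!is_binary) {
    txt <- rawToChar(head[head != as.raw(0)])
    if (grepl("^\\s*solid", txt)) return(read_stl_ascii(path))
    stop("malformed STL: not ASCII (no 'solid' keyword at offset 0) and ",
         "binary facet count at byte offset 80 inconsistent with file size ", size)
  }
  tri <- matrix(numeric(0), 0, 9)
  if (nfac > 0) {
    rec <- readBin(con, "raw", 50 * as.numeric(nfac))
    if (length(rec) < 50 * nfac) {
      stop("malformed binary STL: truncated at byte offset ", 84 + length(rec))
    }
    dim(rec) <- c(50, nfac)
    floats <- readBin(as.vector(rec[1:48, ]), "double", n = 12 * nfac,
                      size = 4, endian = "little")
    dim(floats) <- c(12, nfac)
    tri <- t(floats[4:12, , drop = FALSE])  # drop stored normals
  }
  mesh_from_triangle_soup(tri, warn_empty = nfac == 0)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vx) %% 3 != 0) {
    stop("malformed ASCII STL: vertex count ", length(vx), " not a multiple of 3")
  }
  if (length(vx) == 0) {
    warning("ASCII STL contains no facets: returning empty mesh")
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  nums <- vapply(strsplit(trimws(vx), "\\s+"), function(p) as.numeric(p[2:4]),
                 numeric(3))
  # nums is 3 x (3*nfac) column-major: x1 y1 z1 x2 ... -> 9 values per facet
  tri <- matrix(as.vector(nums), ncol = 9, byrow = TRUE)
  mesh_from_triangle_soup(tri)
}

mesh_from_triangle_soup <- function(tri, warn_empty = FALSE) {
  if (nrow(tri) == 0) {
    if (warn_empty) warning("STL contains zero facets: returning empty mesh")
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  # interleave back to per-face order a1 b1 c1 a2 b2 c2 ...
  n <- nrow(tri)
  ord <- as.vector(rbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n))
  pts <- pts[ord, , drop = FALSE]
  key <- paste(sprintf("%.17g", pts[, 1]), sprintf("%.17g", pts[, 2]),
               sprintf("%.17g", pts[, 3]))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  if (!all(keep)) {
    warning(sum(!keep), " degenerate facet(s) with coincident vertices dropped")
  }
  surface_mesh(pts[first, , drop = FALSE], faces[keep, , drop = FALSE])
}

#' Write an STL file
#'
#' Binary mode writes the standard little-endian layout: 80-byte header,
#' uint32 facet count, then 50 bytes per facet (normal, three vertices as
#' float32, uint16 attribute). Facet normals are recomputed from the face
#' winding; zero-area facets get a zero normal with a warning.
#'
#' @param mesh non-empty [surface_mesh()].
#' @param path output path.
#' @param mode `"binary"` or `"ascii"`.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  if (n_faces(mesh) == 0) stop("refusing to write an empty mesh")
  fn <- face_normals(mesh)
  if (any(fn$areas == 0)) {
    warning(sum(fn$areas == 0), " zero-area facet(s) written with zero normal")
  }
  v <- mesh$vertices
  f <- mesh$faces
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "plateforge binary STL (units: mm)"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- rbind(t(fn$normals), t(v[f[, 1], , drop = FALSE]),
                   t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    raw_f <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    dim(raw_f) <- c(48, nrow(f))
    attr_ <- matrix(as.raw(0), 2, nrow(f))
    writeBin(as.vector(rbind(raw_f, attr_)), con)
  } else {
    lines <- character(0)
    lines <- c(lines, "solid plateforge")
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
                 sprintf("  facet normal %.17g %.17g %.17g",
                         fn$normals[i, 1], fn$normals[i, 2], fn$normals[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "    endloop", "  endfacet")
    }
    lines <- c(lines, "endsolid plateforge")
    writeLines(lines, path)
  }
  invisible(path)
}
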