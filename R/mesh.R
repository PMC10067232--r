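#' Triangle surface mesh
#'
#' The central geometric container of the package: a triangulated surface in
#' millimetres, as exchanged through STL files between the segmentation,
#' virtual-reduction and plate-templating stages.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param validate check structural invariants (indices in range, no
#'   degenerate index triples).
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(vertices) > 0 && ncol(vertices) != 3) {
    stop("vertices must have 3 columns")
  }
  if (nrow(faces) > 0 && ncol(faces) != 3) {
    stop("faces must have 3 columns")
  }
  if (nrow(vertices) == 0) vertices <- matrix(numeric(0), 0, 3)
  if (nrow(faces) == 0) faces <- matrix(integer(0), 0, 3)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  if (nrow(f) == 0) return(invisible(mesh))
  if (min(f) < 1L || max(f) > nv) {
    stop("face indices out of range [1, ", nv, "]")
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("faces with repeated vertex indices are not allowed")
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices)) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

#' Vertex / face counts
#' @param mesh a [surface_mesh()].
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-face normals and areas
#'
#' @param mesh a [surface_mesh()].
#' @param normalize return unit normals (faces with zero area get a zero
#'   normal).
#' @return list with `normals` (n_faces x 3) and `areas` (mm^2).
#' @export
face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  areas <- len / 2
  if (normalize) {
    nz <- len > 0
    cr[nz, ] <- cr[nz, , drop = FALSE] / len[nz]
  }
  list(normals = cr, areas = areas)
}

#' Area-weighted vertex normal(s)
#'
#' The outward normal at a vertex is the normalized area-weighted average of
#' the normals of its incident faces; this is the "normal vector generated
#' from the surface" used to align plate units parallel to the bone.
#'
#' @param mesh an orientation-consistent [surface_mesh()].
#' @param vertex_index single 1-based vertex index, or `NULL` for all.
#' @return unit 3-vector, or an n x 3 matrix when `vertex_index` is `NULL`.
#' @export
vertex_normal <- function(mesh, vertex_index = NULL) {
  fn <- face_normals(mesh, normalize = FALSE)  # length = 2*area, encodes weight
  acc <- matrix(0, n_vertices(mesh), 3)
  f <- mesh$faces
  for (c in 1:3) {
    acc[, 1] <- acc[, 1] + tabulate2(f[, c], fn$normals[, 1], n_vertices(mesh))
    acc[, 2] <- acc[, 2] + tabulate2(f[, c], fn$normals[, 2], n_vertices(mesh))
    acc[, 3] <- acc[, 3] + tabulate2(f[, c], fn$normals[, 3], n_vertices(mesh))
  }
  len <- sqrt(rowSums(acc^2))
  if (is.null(vertex_index)) {
    if (any(len == 0)) stop("mesh has isolated or degenerate vertices")
    return(acc / len)
  }
  if (len[vertex_index] == 0) {
    stop("vertex ", vertex_index, " is isolated (no incident face area)")
  }
  acc[vertex_index, ] / len[vertex_index]
}

# weighted bincount: sum w over entries with index i (length-n result)
tabulate2 <- function(i, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, i)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Total surface area (mm^2)
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) sum(face_normals(mesh)$areas)

#' Enclosed volume by the divergence theorem (mm^3)
#'
#' Signed tetrahedron sum; meaningful for closed, consistently wound meshes
#' (positive when outward-oriented).
#' @param mesh a [surface_mesh()].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Is the mesh watertight?
#'
#' Every edge must be shared by exactly two faces.
#' @param mesh a [surface_mesh()].
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Repair face winding consistency
#'
#' Propagates a consistent winding across shared edges within each shell;
#' closed shells are then globally flipped, if needed, so the signed volume
#' is positive (outward normals).
#' @param mesh a [surface_mesh()].
#' @export
repair_orientation <- function(mesh) {
  if (n_faces(mesh) == 0) return(mesh)
  mesh$faces <- cpp_orient_faces(mesh$faces - 1L) + 1L
  if (mesh_is_watertight(mesh) && mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  mesh
}

#' Weld vertices within a tolerance
#'
#' STL reading dedups only exactly equal coordinates; `weld()` merges
#' near-coincident vertices (e.g. from independently generated fragments).
#' @param mesh a [surface_mesh()].
#' @param tolerance merge distance in mm (grid quantization).
#' @export
weld <- function(mesh, tolerance = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tolerance), round(v[, 2] / tolerance),
               round(v[, 3] / tolerance))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  surface_mesh(newv, newf[keep, , drop = FALSE])
}

#' Concatenate meshes (vertex indices offset)
#' @param meshes list of [surface_mesh()] objects.
#' @export
merge_meshes <- function(meshes) {
  stopifnot(length(meshes) >= 1)
  vs <- lapply(meshes, function(m) m$vertices)
  offs <- cumsum(c(0L, vapply(meshes, n_vertices, integer(1))))
  fs <- Map(function(m, o) m$faces + o, meshes, offs[seq_along(meshes)])
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Closest point on a mesh
#'
#' Exhaustive-equivalent point-to-triangle minimization (interior, edges and
#' vertices all considered); ties at edges/vertices resolve to the lowest
#' face index. The reported normal is the face normal of the winning face.
#'
#' @param mesh non-empty [surface_mesh()].
#' @param query a 3-vector, or an n x 3 matrix of query points.
#' @return For one query: list with `point`, `face_index`, `distance`,
#'   `normal`. For a matrix: list of matrices/vectors (`points`,
#'   `face_indices`, `distances`, `normals`).
#' @export
closest_point <- function(mesh, query) {
  stopifnot(n_faces(mesh) > 0)
  single <- is.null(dim(query))
  q <- if (single) matrix(query, 1, 3) else as.matrix(query)
  res <- cpp_closest_points(q, mesh$vertices, mesh$faces - 1L)
  fn <- face_normals(mesh)$normals
  idx <- res$face + 1L
  normals <- fn[idx, , drop = FALSE]
  if (single) {
    list(point = as.numeric(res$point[1, ]), face_index = idx[1],
         distance = res$dist[1], normal = as.numeric(normals[1, ]))
  } else {
    list(points = res$point, face_indices = idx, distances = res$dist,
         normals = normals)
  }
}

#' Deterministic surface sample points
#'
#' Vertices plus a barycentric lattice on each face sized so that the sample
#' count per face is at least `density * area`. Deterministic (no RNG), so
#' clearance computations are reproducible bit-for-bit.
#'
#' @param mesh a [surface_mesh()].
#' @param density target samples per mm^2.
#' @return n x 3 matrix of points on the surface.
#' @export
sample_surface_points <- function(mesh, density = 1) {
  fa <- face_normals(mesh)$areas
  v <- mesh$vertices
  f <- mesh$faces
  out <- list(v)
  # subdivision order m gives (m+1)(m+2)/2 lattice points
  m <- pmax(0L, ceiling(sqrt(2 * density * fa)) - 1L)
  for (ord in sort(unique(m[m > 0L]))) {
    sel <- which(m == ord)
    bar <- barycentric_lattice(ord)
    bar <- bar[bar[, 1] > 0 & bar[, 2] > 0 & bar[, 3] > 0, , drop = FALSE]
    if (nrow(bar) == 0) next
    a <- v[f[sel, 1], , drop = FALSE]
    b <- v[f[sel, 2], , drop = FALSE]
    c <- v[f[sel, 3], , drop = FALSE]
    for (i in seq_len(nrow(bar))) {
      out[[length(out) + 1L]] <-
        bar[i, 1] * a + bar[i, 2] * b + bar[i, 3] * c
    }
  }
  do.call(rbind, out)
}

barycentric_lattice <- function(m) {
  g <- expand.grid(i = 0:m, j = 0:m)
  g <- g[g$i + g$j <= m, ]
  cbind(g$i, g$j, m - g$i - g$j) / m
}

#' Minimum clearance between two meshes
#'
#' The pipeline's central safety quantity: the smallest unsigned distance from
#' surface A to surface B, with an exact triangle-triangle intersection test
#' run first (any intersection means clearance 0). Distances are evaluated at
#' the vertices of A plus deterministic face samples at `sample_density`.
#'
#' @param mesh_a,mesh_b non-empty [surface_mesh()] objects.
#' @param sample_density samples per mm^2 on A's faces.
#' @return non-negative scalar distance in mm.
#' @export
min_clearance <- function(mesh_a, mesh_b, sample_density = 1) {
  stopifnot(n_faces(mesh_a) > 0, n_faces(mesh_b) > 0)
  if (cpp_meshes_intersect(mesh_a$vertices, mesh_a$faces - 1L,
                           mesh_b$vertices, mesh_b$faces - 1L)) {
    return(0)
  }
  pts <- sample_surface_points(mesh_a, sample_density)
  res <- cpp_closest_points(pts, mesh_b$vertices, mesh_b$faces - 1L)
  min(res$dist)
}

#' Points inside a closed mesh
#'
#' Ray-parity test with a fixed (irrational-direction) ray.
#' @param mesh closed [surface_mesh()].
#' @param points n x 3 matrix.
#' @return logical vector.
#' @export
points_in_mesh <- function(mesh, points) {
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  cpp_points_in_mesh(p, mesh$vertices, mesh$faces - 1L)
}
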