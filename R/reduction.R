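#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation 3-vector, mm.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal (R'R != I)")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation has det != +1 (improper rotation)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a rotation matrix (radians)
#' @param R 3x3 rotation matrix.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Axis-angle rotation matrix
#' @param axis 3-vector (normalized internally).
#' @param angle radians.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b [rigid_transform()] objects.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Inverse rigid transform
#' @param t a [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#' @param points n x 3 matrix or 3-vector.
#' @param t a [rigid_transform()].
#' @export
transform_points <- function(points, t) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(t$rotation)
  out <- sweep(out, 2, t$translation, "+")
  if (single) as.numeric(out) else out
}

#' Apply a rigid transform to a mesh
#'
#' Vertices map v -> R v + t; topology unchanged (an isometry, so all edge
#' lengths are preserved).
#' @param mesh a [surface_mesh()].
#' @param t a [rigid_transform()].
#' @export
apply_transform <- function(mesh, t) {
  mesh$vertices <- transform_points(mesh$vertices, t)
  mesh
}

#' Mirror plane
#' @param point any point on the plane, mm.
#' @param normal plane normal (normalized internally).
#' @export
mirror_plane <- function(point, normal) {
  n <- as.numeric(normal)
  len <- sqrt(sum(n^2))
  if (len == 0) stop("plane normal must be nonzero")
  structure(list(point = as.numeric(point), normal = n / len),
            class = "mirror_plane")
}

#' Reflect a mesh across a plane (mirror technique)
#'
#' Reflection reverses handedness, so face winding is flipped to keep the
#' outward orientation. Used to mirror the intact hemipelvis across the
#' mid-sagittal plane as a reduction target.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [mirror_plane()].
#' @export
mirror_mesh <- function(mesh, plane) {
  v <- mesh$vertices
  d <- (v - matrix(plane$point, nrow(v), 3, byrow = TRUE)) %*% plane$normal
  mesh$vertices <- v - 2 * as.numeric(d) %o% plane$normal
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Default mid-sagittal mirror plane of a mesh
#'
#' x = centroid_x, normal along +x (LPS first axis); always overridable.
#' @param mesh a [surface_mesh()].
#' @export
midsagittal_plane <- function(mesh) {
  mirror_plane(c(mean(mesh$vertices[, 1]), 0, 0), c(1, 0, 0))
}

#' Landmark-based rigid alignment (Kabsch)
#'
#' Least-squares rigid transform mapping `source_points` onto
#' `target_points` via SVD of the cross-covariance, with the reflection
#' corrected so the result is a proper rotation. Realizes "manual
#' repositioning" non-interactively from corresponding landmark pairs.
#'
#' @param source_points,target_points n x 3 matrices, n >= 3, corresponding
#'   rows, not collinear.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd` (mm).
#' @export
kabsch_align <- function(source_points, target_points) {
  s <- as.matrix(source_points)
  t_ <- as.matrix(target_points)
  if (nrow(s) != nrow(t_)) stop("point sets must have equal counts")
  if (nrow(s) < 3) stop("need at least 3 correspondences")
  cs <- colMeans(s)
  ct <- colMeans(t_)
  s0 <- sweep(s, 2, cs)
  t0 <- sweep(t_, 2, ct)
  # collinearity check: second singular value of centered source
  sv <- svd(s0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("landmarks are collinear or degenerate; rotation is not determined")
  }
  H <- crossprod(s0, t0)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  D <- diag(c(1, 1, d))
  R <- dec$v %*% D %*% t(dec$u)
  tr <- ct - as.numeric(R %*% cs)
  tf <- rigid_transform(R, tr)
  resid <- transform_points(s, tf) - t_
  list(transform = tf, rmsd = sqrt(mean(rowSums(resid^2))))
}

#' Optional ICP refinement of a rigid transform
#'
#' Iterative closest point from a starting transform: correspondences from
#' source vertices to closest points on the target, re-solved by Kabsch until
#' the RMSD change falls below `tol`. Off by default in the pipeline; exists
#' for when landmark pairs alone are too sparse.
#'
#' @param source_mesh,target_mesh [surface_mesh()] objects.
#' @param init starting [rigid_transform()].
#' @param max_iterations,tol stopping controls.
#' @export
icp_refine <- function(source_mesh, target_mesh, init = rigid_transform(),
                       max_iterations = 30, tol = 1e-7) {
  tf <- init
  prev <- Inf
  pts <- source_mesh$vertices
  for (i in seq_len(max_iterations)) {
    moved <- transform_points(pts, tf)
    cp <- closest_point(target_mesh, moved)
    fit <- kabsch_align(pts, cp$points)
    tf <- fit$transform
    if (abs(prev - fit$rmsd) < tol) break
    prev <- fit$rmsd
  }
  tf
}

#' Compose transformed fragments into one model
#'
#' Applies each fragment's transform and concatenates, producing the reduced
#' anatomical model. Per-fragment vertex ranges are retained as metadata.
#'
#' @param fragments list of `list(mesh = , transform = )`; `transform` may be
#'   omitted for identity.
#' @return a [surface_mesh()] with attribute `fragment_ranges`.
#' @export
compose_model <- function(fragments) {
  if (length(fragments) == 0) stop("need at least one fragment")
  moved <- lapply(fragments, function(fr) {
    tf <- if (is.null(fr$transform)) rigid_transform() else fr$transform
    apply_transform(fr$mesh, tf)
  })
  out <- merge_meshes(moved)
  nv <- vapply(moved, n_vertices, integer(1))
  ends <- cumsum(nv)
  starts <- c(1L, head(ends, -1) + 1L)
  attr(out, "fragment_ranges") <- Map(function(s, e) c(s, e), starts, ends)
  out
}
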