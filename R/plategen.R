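#' Plate unit specification
#'
#' Parametric geometry of one screw-hole-bearing plate unit. The shipped
#' catalog entries are named for the four library families but their
#' dimensions are repository defaults emulating a generic 3.5 mm pelvic
#' reconstruction plate -- they are NOT vendor data.
#'
#' @param catalog_id identifier string.
#' @param unit_length,width,thickness block dimensions, mm.
#' @param hole_diameter screw hole diameter, mm (< width).
#' @param hole_segments facets of the polygonal hole wall.
#' @param standoff nominal gap between plate underside and bone, mm.
#' @param clearance_threshold minimum allowed plate-bone distance, mm
#'   (<= standoff).
#' @export
plate_unit_spec <- function(catalog_id = "generic",
                            unit_length = 12, width = 10, thickness = 2.8,
                            hole_diameter = 3.6, hole_segments = 32,
                            standoff = 0.5, clearance_threshold = 0.2) {
  dims <- c(unit_length = unit_length, width = width, thickness = thickness,
            hole_diameter = hole_diameter, standoff = standoff,
            clearance_threshold = clearance_threshold)
  if (any(dims <= 0)) {
    bad <- names(dims)[dims <= 0][1]
    stop("plate unit '", catalog_id, "': field ", bad, " must be > 0")
  }
  if (hole_diameter >= width) {
    stop("plate unit '", catalog_id, "': hole_diameter (", hole_diameter,
         ") must be smaller than width (", width, ")")
  }
  if (clearance_threshold > standoff) {
    stop("plate unit '", catalog_id, "': clearance_threshold must not exceed standoff")
  }
  if (hole_segments < 3) {
    stop("plate unit '", catalog_id, "': hole_segments must be >= 3")
  }
  structure(list(catalog_id = catalog_id, unit_length = unit_length,
                 width = width, thickness = thickness,
                 hole_diameter = hole_diameter,
                 hole_segments = as.integer(hole_segments),
                 standoff = standoff,
                 clearance_threshold = clearance_threshold),
            class = "plate_unit_spec")
}

#' Default plate-unit catalog
#'
#' Four placeholder entries named for the library families (Civic, DePuy
#' Synthes, Zimmer, In-house Design). All dimensions are repository
#' defaults, not vendor specifications.
#' @export
default_unit_library <- function() {
  list(
    civic = plate_unit_spec("civic", 12, 10, 2.8, 3.6),
    depuy_synthes = plate_unit_spec("depuy_synthes", 12, 11, 3.0, 3.6),
    zimmer = plate_unit_spec("zimmer", 13, 10, 2.8, 3.8),
    inhouse = plate_unit_spec("inhouse", 12, 10, 2.5, 3.5)
  )
}

#' Load a plate-unit catalog from JSON
#'
#' The file maps catalog ids to [plate_unit_spec()] fields; every entry is
#' validated and a missing field or violated invariant names the entry.
#' @param path JSON catalog.
#' @export
load_unit_library <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("unit_length", "width", "thickness", "hole_diameter")
  out <- list()
  for (id in names(j)) {
    e <- j[[id]]
    miss <- setdiff(required, names(e))
    if (length(miss)) {
      stop("catalog entry '", id, "': missing field(s) ",
           paste(miss, collapse = ", "))
    }
    out[[id]] <- plate_unit_spec(
      catalog_id = id,
      unit_length = e$unit_length, width = e$width, thickness = e$thickness,
      hole_diameter = e$hole_diameter,
      hole_segments = if (is.null(e$hole_segments)) 32L else e$hole_segments,
      standoff = if (is.null(e$standoff)) 0.5 else e$standoff,
      clearance_threshold = if (is.null(e$clearance_threshold)) 0.2
                            else e$clearance_threshold)
  }
  out
}

#' Save a plate-unit catalog to JSON
#' @param library named list of [plate_unit_spec()].
#' @param path output JSON path.
#' @export
save_unit_library <- function(library, path) {
  j <- lapply(library, function(s) s[setdiff(names(s), "catalog_id")])
  jsonlite::write_json(j, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Watertight mesh of one plate unit
#'
#' Rectangular block `unit_length x width x thickness` centered at the
#' origin (x along the plate, y across, z through the thickness) with a
#' polygonal through-hole of `hole_diameter` along z. The annular top and
#' bottom faces are strip-triangulated between the hole polygon and the
#' outer rectangle (corner rays included so the bounding box is exact).
#'
#' @param spec a [plate_unit_spec()].
#' @return a watertight, outward-oriented [surface_mesh()].
#' @export
unit_mesh <- function(spec) {
  L <- spec$unit_length; W <- spec$width; T <- spec$thickness
  r <- spec$hole_diameter / 2
  n <- spec$hole_segments
  # ring angles: n hole facets; the 4 rectangle corner directions are forced
  # into the angle set so the outer boundary passes through the corners
  corner <- atan2(c(W, W, -W, -W) / 2, c(L, -L, -L, L) / 2) %% (2 * pi)
  base <- (2 * pi * (seq_len(n) - 1) / n + pi / n) %% (2 * pi)
  ang <- sort(unique(c(round(base, 12), round(corner, 12))))
  m <- length(ang)
  # outer boundary: intersection of the direction ray with the rectangle
  outer_xy <- t(vapply(ang, function(a) {
    d <- c(cos(a), sin(a))
    tx <- if (abs(d[1]) > 1e-15) (L / 2) / abs(d[1]) else Inf
    ty <- if (abs(d[2]) > 1e-15) (W / 2) / abs(d[2]) else Inf
    d * min(tx, ty)
  }, numeric(2)))
  inner_xy <- cbind(r * cos(ang), r * sin(ang))
  zt <- T / 2; zb <- -T / 2
  # vertex layout: [outer top, inner top, outer bottom, inner bottom]
  V <- rbind(cbind(outer_xy, zt), cbind(inner_xy, zt),
             cbind(outer_xy, zb), cbind(inner_xy, zb))
  ot <- function(i) i
  it <- function(i) m + i
  ob <- function(i) 2 * m + i
  ib <- function(i) 3 * m + i
  faces <- list()
  nxt <- c(seq_len(m)[-1], 1L)
  for (i in seq_len(m)) {
    j <- nxt[i]
    # top ring (normal +z): CCW in xy
    faces[[length(faces) + 1L]] <- rbind(c(ot(i), ot(j), it(j)),
                                         c(ot(i), it(j), it(i)))
    # bottom ring (normal -z): reversed
    faces[[length(faces) + 1L]] <- rbind(c(ob(i), ib(j), ob(j)),
                                         c(ob(i), ib(i), ib(j)))
    # outer wall (outward)
    faces[[length(faces) + 1L]] <- rbind(c(ot(i), ob(i), ob(j)),
                                         c(ot(i), ob(j), ot(j)))
    # hole wall (faces into the hole)
    faces[[length(faces) + 1L]] <- rbind(c(it(i), it(j), ib(j)),
                                         c(it(i), ib(j), ib(i)))
  }
  mesh <- surface_mesh(V, do.call(rbind, faces))
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Orthonormal unit frame on the path
#'
#' @param origin unit center on the adjusted path, mm.
#' @param tangent,normal,binormal pairwise-orthogonal unit vectors,
#'   right-handed (tangent x normal = binormal).
#' @export
unit_frame <- function(origin, tangent, normal, binormal) {
  structure(list(origin = as.numeric(origin), tangent = as.numeric(tangent),
                 normal = as.numeric(normal), binormal = as.numeric(binormal)),
            class = "unit_frame")
}

#' Compute unit frames along the adjusted path
#'
#' Unit i (1-based) is centered at arc length (i - 0.5) * unit_length. The
#' tangent is the local central difference of the path; the normal is the
#' bone surface normal at the closest point, sign-matched to the previous
#' frame (first frame: outward per mesh orientation); at bridge stations the
#' normal is interpolated between the bounding on-surface frames. Normals
#' are Gram-Schmidt orthogonalized against the tangent and the binormal is
#' tangent x normal.
#'
#' @param path adjusted [surface_path()] with `arc_length = unit_count *
#'   unit_length` (within 1e-6).
#' @param mesh the bone [surface_mesh()].
#' @param unit_count number of plate units.
#' @param unit_length unit length, mm.
#' @return list of [unit_frame()] objects.
#' @export
compute_frames <- function(path, mesh, unit_count, unit_length) {
  S <- arc_length(path)
  if (abs(S - unit_count * unit_length) > 1e-6) {
    stop("path length ", S, " != unit_count * unit_length = ",
         unit_count * unit_length, "; run match_length first")
  }
  stations <- (seq_len(unit_count) - 0.5) * unit_length
  info <- lapply(stations, function(s) path_point_at(path, s))
  tangents <- lapply(info, `[[`, "tangent")
  origins <- lapply(info, `[[`, "point")
  on_surf <- vapply(info, `[[`, logical(1), "on_surface")
  vn <- vertex_normal(mesh)  # smooth per-vertex normals, interpolated below
  normals <- vector("list", unit_count)
  prev_n <- NULL
  for (i in seq_len(unit_count)) {
    if (on_surf[i]) {
      cp <- closest_point(mesh, origins[[i]])
      nrm <- interpolated_normal(mesh, vn, cp$point, cp$face_index)
      if (!is.null(prev_n) && sum(nrm * prev_n) < 0) nrm <- -nrm
      normals[[i]] <- nrm
      prev_n <- nrm
    }
  }
  # bridge stations: interpolate between bounding on-surface frames
  if (any(!on_surf)) {
    if (!any(on_surf)) stop("no on-surface station; cannot orient units")
    idx_on <- which(on_surf)
    for (i in which(!on_surf)) {
      before <- idx_on[idx_on < i]
      after <- idx_on[idx_on > i]
      if (length(before) == 0) {
        normals[[i]] <- normals[[after[1]]]
      } else if (length(after) == 0) {
        normals[[i]] <- normals[[before[length(before)]]]
      } else {
        b <- before[length(before)]; a <- after[1]
        t <- (i - b) / (a - b)
        nrm <- (1 - t) * normals[[b]] + t * normals[[a]]
        normals[[i]] <- nrm / sqrt(sum(nrm^2))
      }
    }
    # enforce no flips through the interpolated run
    for (i in 2:unit_count) {
      if (sum(normals[[i]] * normals[[i - 1]]) < 0) {
        normals[[i]] <- -normals[[i]]
      }
    }
  }
  frames <- vector("list", unit_count)
  for (i in seq_len(unit_count)) {
    t_ <- tangents[[i]]
    nrm <- normals[[i]]
    nrm <- nrm - sum(nrm * t_) * t_
    nl <- sqrt(sum(nrm^2))
    if (nl < 1e-9) stop("surface normal parallel to tangent at unit ", i)
    nrm <- nrm / nl
    b <- c(t_[2] * nrm[3] - t_[3] * nrm[2],
           t_[3] * nrm[1] - t_[1] * nrm[3],
           t_[1] * nrm[2] - t_[2] * nrm[1])
    frames[[i]] <- unit_frame(origins[[i]], t_, nrm, b)
  }
  frames
}

# Phong-style smooth surface normal: barycentric interpolation of the
# area-weighted vertex normals within the containing face.  Face normals
# alone tilt by half the tessellation step, which is too coarse for the
# "parallel to the bone surface" alignment contract.
interpolated_normal <- function(mesh, vertex_normals, point, face_index) {
  tri <- mesh$faces[face_index, ]
  a <- mesh$vertices[tri[1], ]
  b <- mesh$vertices[tri[2], ]
  c_ <- mesh$vertices[tri[3], ]
  v0 <- b - a; v1 <- c_ - a; v2 <- point - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  if (abs(den) < 1e-30) {
    n <- face_normals(mesh)$normals[face_index, ]
    return(n)
  }
  w2 <- (d11 * d20 - d01 * d21) / den
  w3 <- (d00 * d21 - d01 * d20) / den
  w <- c(1 - w2 - w3, w2, w3)
  w <- pmin(pmax(w, 0), 1)
  n <- w[1] * vertex_normals[tri[1], ] + w[2] * vertex_normals[tri[2], ] +
    w[3] * vertex_normals[tri[3], ]
  n / sqrt(sum(n^2))
}

# indices of faces whose bounding box overlaps [lo, hi]
local_faces <- function(mesh, lo, hi) {
  v <- mesh$vertices
  f <- mesh$faces
  x1 <- v[f[, 1], 1]; x2 <- v[f[, 2], 1]; x3 <- v[f[, 3], 1]
  y1 <- v[f[, 1], 2]; y2 <- v[f[, 2], 2]; y3 <- v[f[, 3], 2]
  z1 <- v[f[, 1], 3]; z2 <- v[f[, 2], 3]; z3 <- v[f[, 3], 3]
  which(pmin(x1, x2, x3) <= hi[1] & pmax(x1, x2, x3) >= lo[1] &
        pmin(y1, y2, y3) <= hi[2] & pmax(y1, y2, y3) >= lo[2] &
        pmin(z1, z2, z3) <= hi[3] & pmax(z1, z2, z3) >= lo[3])
}

pose_unit <- function(unit, frame, spec, extra_offset = 0) {
  R <- cbind(frame$tangent, frame$binormal, frame$normal)
  center <- frame$origin +
    (spec$standoff + spec$thickness / 2 + extra_offset) * frame$normal
  m <- unit
  m$vertices <- m$vertices %*% t(R)
  m$vertices <- sweep(m$vertices, 2, center, "+")
  m
}

#' Resolve plate-bone penetration at one station
#'
#' The unit is nominally placed with its underside at `standoff` along the
#' frame normal. If its clearance to the bone falls below
#' `clearance_threshold` (the anti-penetration threshold), the unit
#' is translated along +normal by the smallest offset achieving the required
#' clearance, found by bisection to 1e-3 mm; orientation never changes.
#'
#' @param frame a [unit_frame()].
#' @param spec a [plate_unit_spec()].
#' @param bone the bone [surface_mesh()].
#' @param sample_density clearance sampling density, per mm^2.
#' @return list with `frame` (unchanged), `offset` (mm) and `clearance` (mm).
#' @export
resolve_penetration <- function(frame, spec, bone, sample_density = 1) {
  unit <- unit_mesh(spec)
  bone_wt <- mesh_is_watertight(bone)
  diag2 <- 2 * sqrt(spec$unit_length^2 + spec$width^2 + spec$thickness^2)
  # crop the bone to this station's reach (all candidate offsets + margin):
  # distances beyond the clearance threshold never matter, so far triangles
  # cannot change any bisection decision
  p0 <- pose_unit(unit, frame, spec, 0)$vertices
  p1 <- pose_unit(unit, frame, spec, diag2)$vertices
  lo <- pmin(apply(p0, 2, min), apply(p1, 2, min)) - 3
  hi <- pmax(apply(p0, 2, max), apply(p1, 2, max)) + 3
  fidx <- local_faces(bone, lo, hi)
  vb <- bone$vertices
  fb <- bone$faces[fidx, , drop = FALSE] - 1L
  clearance_at <- function(off) {
    posed <- pose_unit(unit, frame, spec, off)
    pts <- sample_surface_points(posed, sample_density)
    if (nrow(fb) == 0) return(Inf)
    if (cpp_meshes_intersect(posed$vertices, posed$faces - 1L, vb, fb)) {
      return(0)
    }
    # no surface intersection: the whole unit is on one side of the bone, so
    # a single-point parity test decides inside vs outside
    if (bone_wt && points_in_mesh(bone, pts[1, , drop = FALSE])[1]) return(0)
    d1 <- min(cpp_closest_points(pts, vb, fb)$dist)
    # symmetric term: exact distances from nearby bone vertices to the unit
    # (the unit is piecewise planar, so this is accurate wherever the bone
    # tessellation is dense, and catches gaps between unit samples)
    plo <- apply(posed$vertices, 2, min) - 2
    phi <- apply(posed$vertices, 2, max) + 2
    near <- which(vb[, 1] >= plo[1] & vb[, 1] <= phi[1] &
                  vb[, 2] >= plo[2] & vb[, 2] <= phi[2] &
                  vb[, 3] >= plo[3] & vb[, 3] <= phi[3])
    if (length(near)) {
      d2 <- min(cpp_closest_points(vb[near, , drop = FALSE],
                                   posed$vertices, posed$faces - 1L)$dist)
      d1 <- min(d1, d2)
    }
    d1
  }
  thr <- spec$clearance_threshold
  c0 <- clearance_at(0)
  if (c0 >= thr) {
    return(list(frame = frame, offset = 0, clearance = c0))
  }
  chi <- clearance_at(diag2)
  if (chi < thr) {
    stop("station at (", paste(sprintf("%.1f", frame$origin), collapse = ", "),
         "): clearance ", sprintf("%.3f", chi), " mm still below threshold at ",
         "maximum offset (pathological geometry)")
  }
  lo <- 0; hi <- diag2
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (clearance_at(mid) >= thr) hi <- mid else lo <- mid
  }
  list(frame = frame, offset = hi, clearance = clearance_at(hi))
}

#' Assemble the chained-unit plate template
#'
#' Poses one unit per frame (local x along the path tangent, y along the
#' binormal, z along the surface normal, underside toward the bone),
#' resolves penetration at every station, concatenates the posed units into
#' one mesh and records per-unit screw axes (unit center, normal direction).
#'
#' @param frames list of [unit_frame()] from [compute_frames()].
#' @param spec a [plate_unit_spec()].
#' @param bone the bone [surface_mesh()].
#' @param sample_density clearance sampling density, per mm^2.
#' @return a `plate_template` object: list with `spec`, `frames`, `offsets`,
#'   `mesh`, `screw_axes`, `clearances`, `metadata`.
#' @export
assemble_template <- function(frames, spec, bone, sample_density = 1) {
  stopifnot(length(frames) >= 1)
  unit <- unit_mesh(spec)
  offsets <- numeric(length(frames))
  clear <- numeric(length(frames))
  posed <- vector("list", length(frames))
  failures <- character(0)
  for (i in seq_along(frames)) {
    res <- tryCatch(resolve_penetration(frames[[i]], spec, bone, sample_density),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("unit ", i, ": ", conditionMessage(res)))
      next
    }
    offsets[i] <- res$offset
    clear[i] <- res$clearance
    posed[[i]] <- pose_unit(unit, frames[[i]], spec, res$offset)
  }
  if (length(failures)) {
    stop("penetration could not be resolved at station(s):\n  ",
         paste(failures, collapse = "\n  "))
  }
  mesh <- merge_meshes(posed)
  screw_axes <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    list(point = f$origin + (spec$standoff + spec$thickness / 2 + offsets[i]) *
           f$normal,
         direction = f$normal)
  })
  # inter-unit bend angles, recorded so the surgeon can check that bends
  # fall between screw holes on the metal plate
  bends <- if (length(frames) > 1) {
    vapply(seq_len(length(frames) - 1), function(i) {
      acos(max(-1, min(1, sum(frames[[i]]$tangent * frames[[i + 1]]$tangent)))) *
        180 / pi
    }, numeric(1))
  } else numeric(0)
  structure(list(spec = spec, frames = frames, offsets = offsets,
                 mesh = mesh, screw_axes = screw_axes, clearances = clear,
                 metadata = list(unit_count = length(frames),
                                 bend_angles_deg = bends,
                                 sample_density = sample_density)),
            class = "plate_template")
}

#' @export
print.plate_template <- function(x, ...) {
  cat(sprintf("<plate_template> %d unit(s) of '%s', min station clearance %.3f mm\n",
              length(x$frames), x$spec$catalog_id, min(x$clearances)))
  invisible(x)
}

#' Export a template as binary STL plus a JSON sidecar
#'
#' The sidecar records frames, unit spec, per-unit offsets and clearances,
#' and screw axes for provenance.
#'
#' @param template a `plate_template`.
#' @param path output STL path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
export_template <- function(template, path) {
  write_stl(template$mesh, path, mode = "binary")
  sidecar <- sub("\\.stl$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(spec = template$spec[setdiff(names(template$spec), "")],
         frames = lapply(template$frames, function(f) {
           list(origin = f$origin, tangent = f$tangent, normal = f$normal,
                binormal = f$binormal)
         }),
         offsets = template$offsets,
         clearances = template$clearances,
         screw_axes = template$screw_axes,
         metadata = template$metadata),
    sidecar, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(stl = path, sidecar = sidecar))
}
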