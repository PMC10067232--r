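#' Parametric phantom surfaces with known ground truth
#'
#' Generates the test anatomy used throughout the package: spheres, torus
#' segments, swept elliptical tubes (a superior-pubic-ramus *analog*, not a
#' pelvis model) and open flat grids. Phantoms are analytic and
#' deterministic: the same spec always yields a bit-identical mesh.
#'
#' @param kind one of `"sphere"`, `"torus_segment"`, `"swept_tube"`,
#'   `"flat_grid"`.
#' @param size named size parameters, mm:
#'   * sphere: `radius` (default 10)
#'   * torus_segment: `major_radius` (60), `minor_radius` (7.5),
#'     `arc_deg` (120)
#'   * swept_tube: `arc_radius` (60), `section_a` (7.5), `section_b` (6),
#'     `arc_deg` (120) -- elliptical section 15 x 12 mm swept along a
#'     circular arc
#'   * flat_grid: `size_x` (100), `size_y` (100)
#' @param resolution target edge length, mm.
#' @param center translation applied to the finished phantom, mm.
#' @return a [surface_mesh()]; watertight except `flat_grid`.
#' @export
make_phantom <- function(kind = c("sphere", "torus_segment", "swept_tube",
                                  "flat_grid"),
                         size = list(), resolution = 2,
                         center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  p <- function(name, default) if (is.null(size[[name]])) default else size[[name]]
  mesh <- switch(kind,
    sphere = icosphere(p("radius", 10), resolution),
    torus_segment = swept_tube_mesh(p("major_radius", 60),
                                    p("minor_radius", 7.5),
                                    p("minor_radius", 7.5),
                                    p("arc_deg", 120), resolution),
    swept_tube = swept_tube_mesh(p("arc_radius", 60), p("section_a", 7.5),
                                 p("section_b", 6), p("arc_deg", 120),
                                 resolution),
    flat_grid = flat_grid_mesh(p("size_x", 100), p("size_y", 100), resolution))
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(center), "+")
  mesh
}

# subdivided icosahedron scaled to radius; subdivision depth chosen so the
# edge length is at most `resolution`
icosphere <- function(radius, resolution) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # icosahedron edge length at unit radius ~1.0515; halves per subdivision
  edge <- 1.0514622 * radius
  depth <- 0
  while (edge > resolution && depth < 7) {
    edge <- edge / 2
    depth <- depth + 1
  }
  for (d in seq_len(depth)) {
    mids <- new.env()
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- mids[[key]]
      if (!is.null(idx)) return(idx)
      m <- vlist[[a]] + vlist[[b]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      idx <- length(vlist)
      assign(key, idx, envir = mids)
      idx
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  m <- surface_mesh(v * radius, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# elliptical section (a along the arc-plane normal direction is b; a in
# plane) swept along a circular arc of radius `arc_radius` in the xy plane,
# capped at both ends
swept_tube_mesh <- function(arc_radius, section_a, section_b, arc_deg,
                            resolution) {
  arc <- arc_deg * pi / 180
  n_along <- max(8L, ceiling(arc_radius * arc / resolution))
  n_around <- max(12L, ceiling(2 * pi * max(section_a, section_b) / resolution))
  ts <- seq(0, arc, length.out = n_along + 1L)
  ph <- 2 * pi * (seq_len(n_around) - 1L) / n_around
  verts <- matrix(0, (n_along + 1L) * n_around, 3)
  for (i in seq_along(ts)) {
    t <- ts[i]
    c0 <- c(arc_radius * cos(t), arc_radius * sin(t), 0)
    e_r <- c(cos(t), sin(t), 0)     # radial, in arc plane
    e_z <- c(0, 0, 1)
    ring <- t(vapply(ph, function(a) {
      c0 + section_a * cos(a) * e_r + section_b * sin(a) * e_z
    }, numeric(3)))
    verts[((i - 1L) * n_around + 1L):(i * n_around), ] <- ring
  }
  idx <- function(i, k) (i - 1L) * n_around + ((k - 1L) %% n_around) + 1L
  faces <- list()
  for (i in seq_len(n_along)) {
    for (k in seq_len(n_around)) {
      a <- idx(i, k); b <- idx(i, k + 1L)
      c_ <- idx(i + 1L, k + 1L); d <- idx(i + 1L, k)
      faces[[length(faces) + 1L]] <- rbind(c(a, b, c_), c(a, c_, d))
    }
  }
  # end caps: fan around the section center
  nv <- nrow(verts)
  verts <- rbind(verts, c(arc_radius, 0, 0),
                 c(arc_radius * cos(arc), arc_radius * sin(arc), 0))
  c1 <- nv + 1L; c2 <- nv + 2L
  for (k in seq_len(n_around)) {
    faces[[length(faces) + 1L]] <- rbind(
      c(c1, idx(1L, k + 1L), idx(1L, k)),
      c(c2, idx(n_along + 1L, k), idx(n_along + 1L, k + 1L)))
  }
  m <- surface_mesh(verts, do.call(rbind, faces))
  m <- repair_orientation(m)
  m
}

flat_grid_mesh <- function(size_x, size_y, resolution) {
  nx <- max(2L, ceiling(size_x / resolution) + 1L)
  ny <- max(2L, ceiling(size_y / resolution) + 1L)
  xs <- seq(-size_x / 2, size_x / 2, length.out = nx)
  ys <- seq(-size_y / 2, size_y / 2, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- matrix(0L, 2L * (nx - 1L) * (ny - 1L), 3)
  rpos <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      faces[rpos, ] <- c(a, b, c_)
      faces[rpos + 1L, ] <- c(a, c_, d)
      rpos <- rpos + 2L
    }
  }
  surface_mesh(v, faces)  # +z normals
}

#' Voxelize a watertight phantom into a two-intensity CT-like volume
#'
#' Voxel centers inside the mesh get `bone_hu`, others `background_hu`. The
#' default spacing (0.8, 0.8, 3.0) mm emulates pelvic CT with sub-millimetre
#' in-plane resolution and 3 mm slices.
#'
#' @param mesh watertight [surface_mesh()].
#' @param spacing 3-vector mm.
#' @param bone_hu,background_hu intensities (defaults 1200 / -100).
#' @param margin voxels of background padding around the mesh bounds.
#' @return a [voxel_volume()].
#' @export
voxelize_phantom <- function(mesh, spacing = c(0.8, 0.8, 3.0),
                             bone_hu = 1200, background_hu = -100,
                             margin = 3L) {
  if (!mesh_is_watertight(mesh)) {
    stop("voxelization needs a watertight (closed) mesh")
  }
  bb <- apply(mesh$vertices, 2, range)
  n <- pmax(1L, ceiling((bb[2, ] - bb[1, ]) / spacing) + 2L * margin)
  origin <- bb[1, ] - (margin - 0.5) * spacing
  xs <- origin[1] + (seq_len(n[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  inside <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, xs, ys, zs)
  if (!any(inside)) {
    warning("mesh encloses no voxel centers at this spacing")
  }
  arr <- array(ifelse(inside, bone_hu, background_hu), dim = n)
  voxel_volume(arr, spacing, origin)
}

#' Cut a phantom by a plane and displace one fragment (simulated fracture)
#'
#' The mesh is clipped by the plane, both open cross-sections are capped
#' (fan triangulation; cross-sections of the shipped phantoms are convex),
#' and the fragment on the positive side of the plane normal is moved by
#' `displacement`. The returned ground truth records the cut plane and the
#' displacement so reduction recovery can be verified exactly.
#'
#' @param mesh watertight [surface_mesh()].
#' @param plane a [mirror_plane()]-style cut plane.
#' @param displacement a [rigid_transform()] applied to fragment b.
#' @return list with `fragment_a`, `fragment_b` (both watertight),
#'   `truth = list(cut_plane, displacement)`.
#' @export
fracture_phantom <- function(mesh, plane, displacement) {
  sd_ <- as.numeric((mesh$vertices -
                       matrix(plane$point, n_vertices(mesh), 3, byrow = TRUE)) %*%
                      plane$normal)
  if (all(sd_ > 0) || all(sd_ < 0)) stop("cut plane misses the mesh")
  frag_a <- clip_mesh(mesh, sd_, keep_positive = FALSE, plane)
  frag_b <- clip_mesh(mesh, sd_, keep_positive = TRUE, plane)
  frag_b <- apply_transform(frag_b, displacement)
  list(fragment_a = frag_a, fragment_b = frag_b,
       truth = list(cut_plane = plane, displacement = displacement))
}

# clip a closed mesh against the plane (signed distances sd per vertex),
# keeping the requested side, and cap the cut loop(s) by centroid fans
clip_mesh <- function(mesh, sd_, keep_positive, plane) {
  s <- if (keep_positive) sd_ else -sd_
  v <- mesh$vertices
  f <- mesh$faces
  eps <- 1e-12
  newv <- list()
  edge_cache <- new.env()
  cut_vertex <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- edge_cache[[key]]
    if (!is.null(idx)) return(idx)
    t <- s[i] / (s[i] - s[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    newv[[length(newv) + 1L]] <<- p
    idx <- nrow(v) + length(newv)
    assign(key, idx, envir = edge_cache)
    idx
  }
  keepf <- list()
  cut_edges <- list()  # directed edges along the cut boundary of kept side
  for (fi in seq_len(nrow(f))) {
    tri <- f[fi, ]
    si <- s[tri]
    inside <- si >= -eps
    nin <- sum(inside)
    if (nin == 3) {
      keepf[[length(keepf) + 1L]] <- tri
    } else if (nin == 0) {
      next
    } else if (nin == 1) {
      a <- tri[inside][1]
      bc <- tri[!inside]
      # preserve winding: rotate tri so kept vertex first
      ord <- tri[c(which(inside), setdiff(1:3, which(inside)))]
      # rotate original order instead to keep orientation
      w <- which(inside)
      rot <- ((w - 1):(w + 1)) %% 3 + 1
      t2 <- tri[rot]
      pab <- cut_vertex(t2[1], t2[2])
      pca <- cut_vertex(t2[3], t2[1])
      keepf[[length(keepf) + 1L]] <- c(t2[1], pab, pca)
      cut_edges[[length(cut_edges) + 1L]] <- c(pab, pca)
    } else {
      w <- which(!inside)
      rot <- ((w - 1):(w + 1)) %% 3 + 1
      t2 <- tri[rot]  # t2[1] outside, t2[2], t2[3] inside
      pab <- cut_vertex(t2[1], t2[2])
      pca <- cut_vertex(t2[3], t2[1])
      keepf[[length(keepf) + 1L]] <- c(pab, t2[2], t2[3])
      keepf[[length(keepf) + 1L]] <- c(pab, t2[3], pca)
      cut_edges[[length(cut_edges) + 1L]] <- c(pca, pab)
    }
  }
  allv <- rbind(v, do.call(rbind, newv))
  # chain directed cut edges into loops and cap each with a centroid fan
  capf <- list()
  if (length(cut_edges)) {
    ce <- do.call(rbind, cut_edges)
    nxt <- new.env()
    for (i in seq_len(nrow(ce))) assign(as.character(ce[i, 1]), ce[i, 2], nxt)
    used <- new.env()
    for (i in seq_len(nrow(ce))) {
      start <- ce[i, 1]
      if (!is.null(used[[as.character(start)]])) next
      loop <- c(start)
      assign(as.character(start), TRUE, used)
      cur <- nxt[[as.character(start)]]
      while (!is.null(cur) && cur != start) {
        loop <- c(loop, cur)
        assign(as.character(cur), TRUE, used)
        cur <- nxt[[as.character(cur)]]
      }
      if (length(loop) >= 3) {
        ctr <- colMeans(allv[loop, , drop = FALSE])
        allv <- rbind(allv, ctr)
        ci <- nrow(allv)
        for (k in seq_along(loop)) {
          a <- loop[k]
          b <- loop[if (k == length(loop)) 1L else k + 1L]
          # cap normal must face outward = -plane normal on kept side;
          # the directed cut edges already run so that (ci, b, a) closes
          capf[[length(capf) + 1L]] <- c(ci, b, a)
        }
      }
    }
  }
  faces <- do.call(rbind, c(keepf, capf))
  out <- surface_mesh(allv, faces, validate = FALSE)
  drop_unused_vertices(out)
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(map[mesh$faces], ncol = 3))
}

#' Sample noisy anchor points along a curve (simulated surgeon clicks)
#'
#' @param curve either a function `t -> xyz` on \[0, 1\] or an m x 3
#'   polyline (interpolated by arc length).
#' @param n number of anchors (>= 2), at equal parameter spacing.
#' @param noise_sd isotropic Gaussian noise, mm.
#' @param seed RNG seed (local; does not disturb the global RNG state).
#' @return n x 3 matrix of ordered points.
#' @export
sample_anchors <- function(curve, n, noise_sd = 0, seed = 1) {
  stopifnot(n >= 2)
  ts <- seq(0, 1, length.out = n)
  pts <- if (is.function(curve)) {
    t(vapply(ts, curve, numeric(3)))
  } else {
    poly <- as.matrix(curve)
    seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                           poly[-nrow(poly), , drop = FALSE])^2))
    cl <- c(0, cumsum(seg))
    t(vapply(ts * cl[length(cl)], function(s) {
      j <- max(1L, min(findInterval(s, cl), nrow(poly) - 1L))
      tt <- if (cl[j + 1] > cl[j]) (s - cl[j]) / (cl[j + 1] - cl[j]) else 0
      poly[j, ] + tt * (poly[j + 1, ] - poly[j, ])
    }, numeric(3)))
  }
  if (noise_sd > 0) {
    old <- .Random.seed_exists()
    if (old) saved <- get(".Random.seed", envir = .GlobalEnv)
    set.seed(seed)
    pts <- pts + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    if (old) assign(".Random.seed", saved, envir = .GlobalEnv)
  }
  pts
}

.Random.seed_exists <- function() exists(".Random.seed", envir = .GlobalEnv)
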