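# Shared fixtures and independent oracles used across test files.

# axis-aligned unit cube mesh at a given corner offset
cube_mesh <- function(offset = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  v <- sweep(v, 2, as.numeric(offset), "+")
  f <- matrix(c(1, 3, 2, 2, 3, 4, 5, 6, 7, 6, 8, 7,
                1, 2, 5, 2, 6, 5, 3, 7, 4, 4, 7, 8,
                1, 5, 3, 3, 5, 7, 2, 4, 6, 4, 8, 6), ncol = 3, byrow = TRUE)
  repair_orientation(surface_mesh(v, f))
}

# Independent point-to-triangle closest distance: project onto the triangle
# plane; if the foot is outside, take the minimum over the three edge
# segments. A different formulation from the package's Ericson kernel.
oracle_point_tri <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nn <- sum(n^2)
  seg_dist <- function(p, q0, q1) {
    d <- q1 - q0
    t <- sum((p - q0) * d) / sum(d^2)
    t <- max(0, min(1, t))
    sqrt(sum((p - (q0 + t * d))^2))
  }
  edge_min <- min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
  if (nn < 1e-30) return(edge_min)
  foot <- p - (sum((p - a) * n) / nn) * n
  # barycentric test of the foot
  v0 <- c - a; v1 <- b - a; v2 <- foot - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  if (u >= 0 && v >= 0 && u + v <= 1) {
    min(sqrt(sum((p - foot)^2)), edge_min)
  } else {
    edge_min
  }
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# exhaustive closest-point over all faces (the brute-force oracle)
oracle_closest <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- vapply(seq_len(nrow(f)), function(i) {
    oracle_point_tri(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
  }, numeric(1))
  list(dist = min(d), face = which.min(d), all = d)
}

# 6/26-connectivity flood fill on a 3-D logical array (independent oracle
# for split_components)
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  labels <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & (if (connectivity == 6) m == 1 else
                        if (connectivity == 18) m <= 2 else m <= 3), ]
  k <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z] || labels[x, y, z] != 0L) next
    k <- k + 1L
    queue <- matrix(c(x, y, z), 1, 3)
    labels[x, y, z] <- k
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (i in seq_len(nrow(offs))) {
        nb <- cur + offs[i, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- k
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  labels
}

# random triangle mesh (triangle soup around the unit sphere) for oracle
# equivalence tests
random_mesh <- function(n_faces, seed) {
  set.seed(seed)
  v <- matrix(rnorm(9 * n_faces), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * 10
  surface_mesh(v, matrix(seq_len(3 * n_faces), ncol = 3, byrow = TRUE))
}

# for each row of a, distance to the nearest row of b
closest_pairwise <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min(colSums((t(b) - a[i, ])^2)))
  }, numeric(1))
}

# memoized shared heavy fixtures
.fx <- new.env()

fx_tube_bone <- function() {
  if (is.null(.fx$tube_bone)) {
    tube <- make_phantom("swept_tube",
                         list(arc_radius = 40, section_a = 6, section_b = 5,
                              arc_deg = 100), resolution = 2)
    vol <- voxelize_phantom(tube)
    comps <- split_components(threshold_segment(vol, 300))
    .fx$tube_truth <- tube
    .fx$tube_bone <- extract_surface(comps, 1)
  }
  .fx$tube_bone
}

fx_tube_truth <- function() {
  fx_tube_bone()
  .fx$tube_truth
}

# small end-to-end config shared by the pipeline and determinism tests
pipeline_config <- function(outdir) {
  list(
    output_dir = outdir,
    phantom = list(kind = "swept_tube",
                   size = list(arc_radius = 40, section_a = 6, section_b = 5,
                               arc_deg = 100),
                   resolution = 2),
    segment = list(low = 300),
    plan = list(
      anchors = t(vapply(seq(0, 1, length.out = 7), function(t) {
        a <- t * 100 * pi / 180
        c(46 * cos(a), 46 * sin(a), 0)
      }, numeric(3))),
      unit = "civic"))
}

fx_sphere100 <- function() {
  if (is.null(.fx$sphere100)) {
    .fx$sphere100 <- make_phantom("sphere", list(radius = 100), resolution = 4)
  }
  .fx$sphere100
}
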