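#' Path construction parameters
#'
#' @param sample_spacing path sampling step, mm.
#' @param smoothing_lambda Laplacian step in \[0, 1\]; 0 disables smoothing.
#' @param smoothing_iterations smoothing passes.
#' @param wrap_distance samples farther than this from the bone are treated
#'   as gap (bridge) candidates, mm.
#' @param projection_tolerance distance within which a sample counts as "on
#'   the surface", mm.
#' @export
path_params <- function(sample_spacing = 0.5, smoothing_lambda = 0.5,
                        smoothing_iterations = 10, wrap_distance = 5.0,
                        projection_tolerance = 0.1) {
  stopifnot(sample_spacing > 0, smoothing_lambda >= 0, smoothing_lambda <= 1,
            smoothing_iterations >= 0)
  if (wrap_distance <= projection_tolerance) {
    stop("wrap_distance must exceed projection_tolerance")
  }
  structure(list(sample_spacing = sample_spacing,
                 smoothing_lambda = smoothing_lambda,
                 smoothing_iterations = as.integer(smoothing_iterations),
                 wrap_distance = wrap_distance,
                 projection_tolerance = projection_tolerance),
            class = "path_params")
}

#' On-surface plate path
#'
#' Ordered polyline hugging the bone surface, with an arc-length table,
#' per-sample on-surface flags (FALSE = bridge/wrap chord over a reduction
#' gap) and the indices of the samples that are projected anchors.
#'
#' @param samples n x 3 matrix, mm.
#' @param on_surface logical per sample.
#' @param anchor_indices indices into samples.
#' @param proj_dist distance of each raw sample from the surface before
#'   projection (diagnostic, drives wrap decisions).
#' @export
surface_path <- function(samples, on_surface = rep(TRUE, nrow(samples)),
                         anchor_indices = integer(0),
                         proj_dist = rep(0, nrow(samples))) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  stopifnot(ncol(samples) == 3, nrow(samples) >= 2)
  seg <- sqrt(rowSums((samples[-1, , drop = FALSE] -
                         samples[-nrow(samples), , drop = FALSE])^2))
  structure(list(samples = samples,
                 cumulative_length = c(0, cumsum(seg)),
                 on_surface = as.logical(on_surface),
                 anchor_indices = as.integer(anchor_indices),
                 proj_dist = as.numeric(proj_dist)),
            class = "surface_path")
}

#' @export
print.surface_path <- function(x, ...) {
  cat(sprintf("<surface_path> %d samples, %.2f mm, %d bridge sample(s)\n",
              nrow(x$samples), arc_length(x), sum(!x$on_surface)))
  invisible(x)
}

#' Total arc length of a path (mm)
#' @param path a [surface_path()].
#' @export
arc_length <- function(path) {
  path$cumulative_length[length(path$cumulative_length)]
}

#' Project anchor points onto the bone surface
#'
#' Each operator-selected point is replaced by its closest point on the
#' mesh; order is preserved and consecutive duplicates (< 1e-6 mm apart)
#' collapse to one.
#'
#' @param mesh non-empty [surface_mesh()].
#' @param raw_points n x 3 matrix, n >= 2, ordered along the intended plate.
#' @return m x 3 matrix of on-surface anchors.
#' @export
project_anchors <- function(mesh, raw_points) {
  p <- as.matrix(raw_points)
  if (nrow(p) < 2) stop("need at least 2 anchor points")
  proj <- closest_point(mesh, p)$points
  keep <- c(TRUE, sqrt(rowSums((proj[-1, , drop = FALSE] -
                                  proj[-nrow(proj), , drop = FALSE])^2)) >= 1e-6)
  out <- proj[keep, , drop = FALSE]
  if (nrow(out) < 2) {
    stop("fewer than 2 distinct anchors after projection/collapsing")
  }
  out
}

# Uniform Catmull-Rom through the anchor sequence, sampled so consecutive
# samples are at most `spacing` apart (per-segment chord heuristic).
catmull_rom_sample <- function(anchors, spacing) {
  a <- as.matrix(anchors)
  n <- nrow(a)
  ext <- rbind(2 * a[1, ] - a[2, ], a, 2 * a[n, ] - a[n - 1, ])
  out <- list(a[1, , drop = FALSE])
  anchor_rows <- c(1L)
  for (i in seq_len(n - 1)) {
    p0 <- ext[i, ]; p1 <- ext[i + 1, ]; p2 <- ext[i + 2, ]; p3 <- ext[i + 3, ]
    chord <- sqrt(sum((p2 - p1)^2))
    k <- max(1L, ceiling(chord / spacing))
    t <- seq_len(k) / k
    t2 <- t * t; t3 <- t2 * t
    b0 <- -0.5 * t3 + t2 - 0.5 * t
    b1 <- 1.5 * t3 - 2.5 * t2 + 1
    b2 <- -1.5 * t3 + 2 * t2 + 0.5 * t
    b3 <- 0.5 * t3 - 0.5 * t2
    seg <- outer(b0, p0) + outer(b1, p1) + outer(b2, p2) + outer(b3, p3)
    out[[length(out) + 1L]] <- seg
    anchor_rows <- c(anchor_rows, anchor_rows[length(anchor_rows)] + k)
  }
  list(samples = do.call(rbind, out), anchor_rows = anchor_rows)
}

#' Build the on-surface plate path from projected anchors
#'
#' Pipeline: (1) an interpolating Catmull-Rom spline through the anchors,
#' sampled at most `sample_spacing` apart; (2) projection of every sample to
#' the mesh; (3) `smoothing_iterations` passes of endpoint-fixed Laplacian
#' averaging with re-projection after each pass. Anchors are soft: they may
#' drift up to `2 * sample_spacing` from their projected location. Samples
#' whose spline position lies farther than `wrap_distance` from the bone are
#' left unprojected and flagged off-surface for [wrap_path()] to bridge; if
#' an entire inter-anchor segment is off-surface the path is rejected.
#'
#' @param mesh non-empty [surface_mesh()].
#' @param anchors m x 3 on-surface anchors (see [project_anchors()]).
#' @param params a [path_params()].
#' @return a [surface_path()].
#' @export
build_path <- function(mesh, anchors, params = path_params()) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2) stop("need at least 2 anchors")
  cr <- catmull_rom_sample(anchors, params$sample_spacing)
  s <- cr$samples
  proj <- closest_point(mesh, s)
  off <- proj$distances > params$wrap_distance
  # reject only if a whole inter-anchor span diverged
  for (i in seq_len(length(cr$anchor_rows) - 1)) {
    rows <- (cr$anchor_rows[i]):(cr$anchor_rows[i + 1])
    if (all(off[rows])) {
      stop("projection diverged over the whole segment between anchors ", i,
           " and ", i + 1, " (> wrap_distance = ", params$wrap_distance,
           " mm); use wrap_path() on a path with closer anchors, or check ",
           "the reduction")
    }
  }
  cur <- s
  cur[!off, ] <- proj$points[!off, , drop = FALSE]
  anchor_pos <- cur[cr$anchor_rows, , drop = FALSE]
  lam <- params$smoothing_lambda
  if (lam > 0 && params$smoothing_iterations > 0) {
    n <- nrow(cur)
    for (it in seq_len(params$smoothing_iterations)) {
      mid <- (cur[1:(n - 2), , drop = FALSE] + cur[3:n, , drop = FALSE]) / 2
      cur[2:(n - 1), ] <- (1 - lam) * cur[2:(n - 1), , drop = FALSE] + lam * mid
      # soft anchors: clamp drift to 2 * sample_spacing
      lim <- 2 * params$sample_spacing
      for (ai in seq_along(cr$anchor_rows)) {
        r <- cr$anchor_rows[ai]
        if (r == 1L || r == n) next
        dvec <- cur[r, ] - anchor_pos[ai, ]
        dd <- sqrt(sum(dvec^2))
        if (dd > lim) cur[r, ] <- anchor_pos[ai, ] + dvec * (lim / dd)
      }
      pr <- closest_point(mesh, cur)
      onr <- pr$distances <= params$wrap_distance
      cur[onr, ] <- pr$points[onr, , drop = FALSE]
      off <- !onr
    }
  }
  final_d <- closest_point(mesh, cur)$distances
  surface_path(cur, on_surface = !off, anchor_indices = cr$anchor_rows,
               proj_dist = final_d)
}

#' Bridge off-surface runs with straight chords (the wrap function)
#'
#' Maximal runs of off-surface samples are replaced by a straight chord
#' between the bounding on-surface samples, resampled at the path's spacing
#' and flagged `on_surface = FALSE`; everything else is untouched and the
#' arc-length table is rebuilt.
#'
#' @param path a [surface_path()] (e.g. from [build_path()]).
#' @param mesh the bone [surface_mesh()].
#' @param params a [path_params()].
#' @export
wrap_path <- function(path, mesh, params = path_params()) {
  flags <- path$on_surface
  n <- length(flags)
  if (!flags[1] || !flags[n]) {
    stop("path must start and end on the bone surface")
  }
  if (all(flags)) return(path)
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pieces <- list()
  flagpieces <- list()
  cursor <- 1L
  for (ri in seq_along(runs$values)) {
    if (runs$values[ri]) next
    a <- starts[ri] - 1L  # bounding on-surface samples
    b <- ends[ri] + 1L
    # on-surface piece before the gap
    pieces[[length(pieces) + 1L]] <- path$samples[cursor:a, , drop = FALSE]
    flagpieces[[length(flagpieces) + 1L]] <- rep(TRUE, a - cursor + 1L)
    chord <- path$samples[b, ] - path$samples[a, ]
    clen <- sqrt(sum(chord^2))
    k <- max(1L, ceiling(clen / params$sample_spacing))
    t <- seq_len(k - 1L) / k
    if (length(t)) {
      bridge <- matrix(path$samples[a, ], k - 1L, 3, byrow = TRUE) +
        t %o% chord
      pieces[[length(pieces) + 1L]] <- bridge
      flagpieces[[length(flagpieces) + 1L]] <- rep(FALSE, k - 1L)
    }
    cursor <- b
  }
  pieces[[length(pieces) + 1L]] <- path$samples[cursor:n, , drop = FALSE]
  flagpieces[[length(flagpieces) + 1L]] <- rep(TRUE, n - cursor + 1L)
  samples <- do.call(rbind, pieces)
  flags2 <- unlist(flagpieces)
  d <- rep(0, nrow(samples))
  d[flags2] <- 0
  d[!flags2] <- closest_point(mesh, samples[!flags2, , drop = FALSE])$distances
  # anchors: re-locate by nearest sample
  ai <- vapply(path$anchor_indices, function(i) {
    which.min(rowSums(sweep(samples, 2, path$samples[i, ])^2))
  }, integer(1))
  surface_path(samples, on_surface = flags2, anchor_indices = ai,
               proj_dist = d)
}

#' Mid-line crop/lengthen rule: match path length to whole plate units
#'
#' With path length S and unit length L, the residual r = S mod L decides:
#' shorter than the unit mid-line (r < L/2) crops the path down to
#' floor(S/L) units; at or beyond the mid-line (r >= L/2) the path is
#' extended tangentially to ceil(S/L) units. Extension samples re-project to
#' the bone where within `wrap_distance`, else they are bridge-flagged. At
#' least one unit is always returned.
#'
#' @param path a [surface_path()].
#' @param unit_length plate unit length L, mm.
#' @param mesh optional bone mesh for re-projecting extension samples; when
#'   `NULL` extension samples stay on the tangent (bridge-flagged).
#' @param params a [path_params()].
#' @return list with `unit_count` and `adjusted_path`.
#' @export
match_length <- function(path, unit_length, mesh = NULL,
                         params = path_params()) {
  S <- arc_length(path)
  L <- unit_length
  if (S <= 0 || L <= 0) stop("path length and unit length must be positive")
  r <- S %% L
  n_units <- if (r < L / 2) floor(S / L) else ceiling(S / L)
  if (n_units < 1) n_units <- 1
  target <- n_units * L
  if (target <= S) {
    adjusted <- crop_path(path, target)
  } else {
    adjusted <- extend_path(path, target, mesh, params)
  }
  list(unit_count = as.integer(n_units), adjusted_path = adjusted)
}

crop_path <- function(path, target) {
  cl <- path$cumulative_length
  keep <- cl < target - 1e-12
  idx <- max(which(keep))
  s <- path$samples[1:idx, , drop = FALSE]
  flags <- path$on_surface[1:idx]
  d <- path$proj_dist[1:idx]
  # interpolated end point at exact arc length
  if (target > cl[idx] + 1e-12) {
    j <- idx + 1L
    t <- (target - cl[idx]) / (cl[j] - cl[idx])
    endp <- path$samples[idx, ] + t * (path$samples[j, ] - path$samples[idx, ])
    s <- rbind(s, endp)
    flags <- c(flags, path$on_surface[j] && path$on_surface[idx])
    d <- c(d, (1 - t) * path$proj_dist[idx] + t * path$proj_dist[j])
  }
  ai <- path$anchor_indices[path$anchor_indices <= nrow(s)]
  surface_path(s, on_surface = flags, anchor_indices = ai, proj_dist = d)
}

extend_path <- function(path, target, mesh, params) {
  n <- nrow(path$samples)
  tangent <- path$samples[n, ] - path$samples[n - 1, ]
  tl <- sqrt(sum(tangent^2))
  if (tl == 0) stop("degenerate final segment; cannot extend")
  tangent <- tangent / tl
  extra <- target - arc_length(path)
  k <- max(1L, ceiling(extra / params$sample_spacing))
  # grow along the tangent; if a bone mesh is supplied, re-project each new
  # sample so the extension keeps hugging the surface
  new_pts <- matrix(0, k, 3)
  new_flags <- logical(k)
  new_d <- numeric(k)
  prev <- path$samples[n, ]
  produced <- 0
  for (i in seq_len(k)) {
    step <- extra / k
    cand <- prev + tangent * step
    if (!is.null(mesh)) {
      cp <- closest_point(mesh, cand)
      if (cp$distance <= params$wrap_distance) {
        newp <- cp$point
        # keep the arc-length increment equal to the requested step
        dir <- newp - prev
        dl <- sqrt(sum(dir^2))
        if (dl > 1e-12) {
          newp <- prev + dir * (step / dl)
          cp2 <- closest_point(mesh, newp)
          new_pts[i, ] <- newp
          new_flags[i] <- cp2$distance <= params$projection_tolerance ||
            cp2$distance <= params$wrap_distance
          new_d[i] <- cp2$distance
        } else {
          new_pts[i, ] <- prev + tangent * step
          new_flags[i] <- FALSE
          new_d[i] <- cp$distance
        }
        # update tangent to follow the surface
        tangent <- (new_pts[i, ] - prev)
        tangent <- tangent / sqrt(sum(tangent^2))
      } else {
        new_pts[i, ] <- cand
        new_flags[i] <- FALSE
        new_d[i] <- cp$distance
      }
    } else {
      new_pts[i, ] <- cand
      new_flags[i] <- FALSE
      new_d[i] <- NA_real_
    }
    prev <- new_pts[i, ]
    produced <- produced + step
  }
  samples <- rbind(path$samples, new_pts)
  surface_path(samples,
               on_surface = c(path$on_surface, new_flags),
               anchor_indices = path$anchor_indices,
               proj_dist = c(path$proj_dist, ifelse(is.na(new_d), Inf, new_d)))
}

#' Interpolate a point (and local tangent) at a given arc length
#'
#' @param path a [surface_path()].
#' @param s arc length in \[0, arc_length(path)\].
#' @return list with `point`, `tangent` (unit), `on_surface` (logical).
#' @export
path_point_at <- function(path, s) {
  cl <- path$cumulative_length
  total <- cl[length(cl)]
  s <- max(0, min(s, total))
  j <- findInterval(s, cl, rightmost.closed = TRUE)
  j <- max(1L, min(j, nrow(path$samples) - 1L))
  t <- if (cl[j + 1] > cl[j]) (s - cl[j]) / (cl[j + 1] - cl[j]) else 0
  pt <- path$samples[j, ] + t * (path$samples[j + 1, ] - path$samples[j, ])
  # central-difference tangent over one local step
  j0 <- max(1L, j - 1L)
  j1 <- min(nrow(path$samples), j + 2L)
  tan_ <- path$samples[j1, ] - path$samples[j0, ]
  tl <- sqrt(sum(tan_^2))
  if (tl == 0) stop("zero-length tangent at arc length ", s)
  list(point = pt, tangent = tan_ / tl,
       on_surface = path$on_surface[j] && path$on_surface[j + 1])
}

#' Export a path as JSON (samples, flags, anchors)
#' @param path a [surface_path()].
#' @param file output path.
#' @export
write_path_json <- function(path, file) {
  jsonlite::write_json(
    list(samples = unname(as.matrix(path$samples)),
         cumulative_length = path$cumulative_length,
         on_surface = path$on_surface,
         anchor_indices = path$anchor_indices),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read ordered anchor points from JSON or CSV
#'
#' JSON: `[{"x":..,"y":..,"z":..}, ...]` or an n x 3 array. CSV: columns
#' x, y, z. Millimetres, ordered along the intended plate.
#' @param file input path.
#' @export
read_anchors <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    j <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (is.data.frame(j)) {
      return(as.matrix(j[, c("x", "y", "z")]))
    }
    m <- as.matrix(j)
    storage.mode(m) <- "double"
    return(m)
  }
  m <- utils::read.csv(file)
  as.matrix(m[, c("x", "y", "z")])
}
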