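#' Voxel volume
#'
#' A gridded scalar image (HU-like intensities) with physical spacing and
#' origin. The world position of voxel (i, j, k) (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`; axes follow the patient LPS
#' convention used by CT.
#'
#' @param intensities 3-D numeric array.
#' @param spacing 3-vector, mm per voxel, all > 0.
#' @param origin 3-vector, mm, world position of the first voxel center.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(intensities)) == 3, all(dim(intensities) >= 1))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm/voxel)")
  }
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Integer label map
#'
#' Same grid geometry as its source volume; 0 is background and fragment
#' labels are contiguous 1..K.
#'
#' @param labels 3-D integer array.
#' @param spacing,origin grid geometry, as in [voxel_volume()].
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  k <- max(x$labels)
  cat(sprintf("<label_map> %d x %d x %d, %d label(s)\n", d[1], d[2], d[3], k))
  invisible(x)
}

present_labels <- function(lm) sort(setdiff(unique(as.vector(lm$labels)), 0L))

#' Write a volume or label map as NRRD
#'
#' Minimal NRRD0004 writer; encodings `"raw"` (little-endian float64/int32)
#' and `"ascii"`.
#'
#' @param vol a [voxel_volume()] or [label_map()].
#' @param path output `.nrrd` path.
#' @param encoding `"raw"` or `"ascii"`.
#' @export
write_nrrd <- function(vol, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_labels <- inherits(vol, "label_map")
  arr <- if (is_labels) vol$labels else vol$intensities
  d <- dim(arr)
  type <- if (is_labels) "int" else "double"
  hdr <- c("NRRD0004",
           "# plateforge volume (units: mm)",
           paste0("type: ", type),
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(d, collapse = " ")),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", encoding),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (encoding == "raw") {
    if (is_labels) {
      writeBin(as.integer(arr), con, size = 4, endian = "little")
    } else {
      writeBin(as.numeric(arr), con, size = 8, endian = "little")
    }
  } else {
    writeLines(paste(format(as.vector(arr), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports the subset written by [write_nrrd()] plus common scalar types
#' (`uchar`, `short`, `ushort`, `int`, `float`, `double`), raw and ascii
#' encodings, detached headers not supported.
#'
#' @param path `.nrrd` file.
#' @param as_labels return a [label_map()] instead of a [voxel_volume()].
#' @export
read_nrrd <- function(path, as_labels = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- read_line_binary(con)
    if (is.null(line)) stop("malformed NRRD: no blank line ending the header")
    if (line == "") break
    hdr <- c(hdr, line)
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path)
  fields <- hdr[grepl(":", hdr) & !grepl("^#", hdr)]
  get <- function(name) {
    m <- fields[grepl(paste0("^", name, ":"), fields)]
    if (length(m) == 0) return(NULL)
    trimws(sub("^[^:]+:=?", "", m[1]))
  }
  sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3-D NRRD volumes are supported")
  type <- get("type")
  encoding <- get("encoding")
  spacing <- c(1, 1, 1)
  sd <- get("space directions")
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    m <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    spacing <- sqrt(colSums(m^2))
  } else if (!is.null(get("spacings"))) {
    spacing <- as.numeric(strsplit(get("spacings"), "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  so <- get("space origin")
  if (!is.null(so)) {
    origin <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
  }
  n <- prod(sizes)
  if (identical(encoding, "ascii") || identical(encoding, "txt") ||
      identical(encoding, "text")) {
    rest <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.numeric(strsplit(trimws(rest), "\\s+")[[1]])
  } else if (identical(encoding, "raw")) {
    endian <- get("endian")
    endian <- if (identical(endian, "big")) "big" else "little"
    vals <- switch(type,
      "uchar" = , "unsigned char" = , "uint8" =
        as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
      "short" = , "int16" =
        as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
      "ushort" = , "uint16" =
        as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                           endian = endian)),
      "int" = , "int32" = , "signed int" =
        as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
      "float" = readBin(con, "double", n, size = 4, endian = endian),
      "double" = readBin(con, "double", n, size = 8, endian = endian),
      stop("unsupported NRRD type: ", type))
  } else {
    stop("unsupported NRRD encoding: ", encoding)
  }
  if (length(vals) < n) stop("NRRD data shorter than sizes promise")
  arr <- array(vals[seq_len(n)], dim = sizes)
  if (as_labels) {
    label_map(arr, spacing, origin)
  } else {
    voxel_volume(arr, spacing, origin)
  }
}

read_line_binary <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10)) return(sub("\r$", "", rawToChar(bytes)))
    bytes <- c(bytes, b)
  }
}

#' Load a volumetric image
#'
#' Currently NRRD only (the format the synthetic phantom generator writes).
#' DICOM series and NIfTI are not parsed natively; convert externally to
#' NRRD. Slice spacing uniformity is implied by the regular NRRD grid.
#'
#' @param path `.nrrd` file.
#' @return a [voxel_volume()].
#' @export
load_volume <- function(path) {
  if (dir.exists(path)) {
    stop("DICOM directory input is not supported by this build; ",
         "convert the series to NRRD first")
  }
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    stop("unsupported volume format (expected .nrrd): ", path)
  }
  read_nrrd(path)
}

#' Threshold segmentation
#'
#' Foreground iff `low <= intensity <= high` (both bounds inclusive) — the
#' bone/soft-tissue separation by intensity windowing. Monotone: enlarging
#' the window never removes foreground.
#'
#' @param volume a [voxel_volume()].
#' @param low,high inclusive HU bounds; use `-Inf`/`Inf` for open ends.
#' @return a binary [label_map()] (labels 0/1).
#' @export
threshold_segment <- function(volume, low, high = Inf) {
  if (low > high) stop("threshold low (", low, ") must be <= high (", high, ")")
  mask <- volume$intensities >= low & volume$intensities <= high
  label_map(array(as.integer(mask), dim = dim(volume$intensities)),
            volume$spacing, volume$origin)
}

#' Split a binary mask into connected components
#'
#' Components are relabeled 1..K in decreasing voxel-count order (ties broken
#' by the lowest linear index of the first voxel, i.e. discovery order).
#'
#' @param mask binary [label_map()].
#' @param connectivity 6, 18 or 26 (default 26: fragments touching only at
#'   corners across coarse slices are kept together).
#' @return a [label_map()] with labels 1..K.
#' @export
split_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (any(mask$labels > 1L)) stop("split_components expects a binary mask")
  d <- dim(mask$labels)
  raw <- cpp_label_components(as.vector(mask$labels) > 0L, as.integer(d),
                              as.integer(connectivity))
  k <- max(raw, 0L)
  if (k > 0L) {
    counts <- tabulate(raw, nbins = k)
    # order by decreasing size; stable for ties (discovery = first-voxel order)
    remap <- integer(k)
    remap[order(-counts)] <- seq_len(k)
    raw[raw > 0L] <- remap[raw[raw > 0L]]
  }
  label_map(array(raw, dim = d), mask$spacing, mask$origin)
}

#' Erase labels (e.g. remove the femurs before isolating the pelvis)
#'
#' @param labelmap a [label_map()].
#' @param ids labels to set to background; remaining labels are renumbered
#'   contiguously preserving order.
#' @export
erase_labels <- function(labelmap, ids) {
  ids <- as.integer(ids)
  present <- present_labels(labelmap)
  missing <- setdiff(ids, present)
  if (length(missing)) {
    stop("label(s) not present: ", paste(missing, collapse = ", "))
  }
  lab <- labelmap$labels
  lab[lab %in% ids] <- 0L
  remaining <- sort(setdiff(present, ids))
  if (length(remaining)) {
    remap <- integer(max(remaining))
    remap[remaining] <- seq_along(remaining)
    nz <- lab > 0L
    lab[nz] <- remap[lab[nz]]
  }
  label_map(lab, labelmap$spacing, labelmap$origin)
}

#' Extract an isosurface mesh for one label
#'
#' Marching tetrahedra on the binary indicator of the label at iso-value 0.5.
#' Because a hard 0/1 indicator puts every surface vertex at an edge
#' midpoint, the raw extraction has a large systematic surface-area bias
#' (staircase effect); by default the indicator is first anti-aliased with a
#' small Gaussian (`anti_alias_sigma`, mm) and the mesh is then relaxed with
#' volume-preserving Taubin smoothing, which brings sphere-phantom area and
#' volume within a few percent of analytic at CT-like spacings. Set both to
#' zero for the raw midpoint isosurface.
#'
#' @param labelmap a [label_map()].
#' @param label which label to extract.
#' @param anti_alias_sigma Gaussian pre-smoothing of the indicator, mm
#'   (default 1.0; 0 disables).
#' @param smooth_iterations Taubin smoothing passes (default 10; 0 disables).
#' @return a watertight, outward-oriented [surface_mesh()] in mm.
#' @export
extract_surface <- function(labelmap, label, anti_alias_sigma = 1.0,
                            smooth_iterations = 10) {
  if (!label %in% labelmap$labels) stop("label ", label, " not present")
  ind <- array(as.numeric(labelmap$labels == label), dim = dim(labelmap$labels))
  # pad so surfaces at the grid border close properly
  ind <- pad_array(ind, 2L)
  if (anti_alias_sigma > 0) {
    ind <- gaussian_smooth_3d(ind, anti_alias_sigma / labelmap$spacing)
  }
  res <- cpp_marching_tets(as.vector(ind), dim(ind), 0.5)
  if (nrow(res$faces) == 0) {
    stop("label ", label, " produced no isosurface (feature thinner than a voxel?)")
  }
  # index space (0-based, padded) -> world mm
  v <- res$vertices
  v <- sweep(v, 2, c(2, 2, 2))                 # remove padding
  v <- sweep(v, 2, labelmap$spacing, "*")
  v <- sweep(v, 2, labelmap$origin, "+")
  mesh <- surface_mesh(v, res$faces + 1L)
  if (smooth_iterations > 0) {
    mesh <- taubin_smooth(mesh, iterations = smooth_iterations)
  }
  mesh
}

pad_array <- function(a, n) {
  d <- dim(a)
  out <- array(0, d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- a
  out
}

# separable Gaussian, sigma per axis in voxels, replicate-free zero padding
# (fine for indicator fields embedded in a zero background)
gaussian_smooth_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 1e-9) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- convolve_axis(a, k, axis)
  }
  a
}

convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (t in seq_along(k)) {
    off <- t - r - 1L
    src <- seq_len(dp[1]) + off
    ok <- src >= 1L & src <= dp[1]
    out[ok, ] <- out[ok, ] + k[t] * m[src[ok], ]
  }
  ap <- array(out, dim = dp)
  aperm(ap, order(perm))
}

#' Taubin lambda/mu mesh smoothing
#'
#' Two-step (shrink, inflate) Laplacian smoothing that relaxes staircase
#' artifacts while approximately preserving enclosed volume.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda+mu pairs.
#' @param lambda,mu step sizes (defaults 0.5 / -0.53).
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  e <- unique(e)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(v), nrow(v)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    for (step in c(lambda, mu)) {
      avg <- as.matrix(A %*% v) / deg
      v <- v + step * (avg - v)
    }
  }
  surface_mesh(v, f)
}
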