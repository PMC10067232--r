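test_that("mirror_mesh is an involution preserving edge lengths", {
  s <- make_phantom("sphere", list(radius = 6), resolution = 1,
                    center = c(5, -2, 3))
  pl <- mirror_plane(c(1, 1, 0), c(2, -1, 0.5))
  once <- mirror_mesh(s, pl)
  twice <- mirror_mesh(once, pl)
  expect_lt(max(abs(twice$vertices - s$vertices)), 1e-12)
  expect_identical(twice$faces, s$faces)
  # isometry: edge lengths exactly preserved
  e <- s$faces[, 1:2]
  len0 <- sqrt(rowSums((s$vertices[e[, 1], ] - s$vertices[e[, 2], ])^2))
  len1 <- sqrt(rowSums((once$vertices[e[, 1], ] - once$vertices[e[, 2], ])^2))
  expect_equal(len1, len0, tolerance = 1e-12)
  # orientation preserved: volume still positive
  expect_gt(mesh_volume(once), 0)
})

test_that("mirror fixes points on the plane and maps cube across x = 0", {
  pl <- mirror_plane(c(0, 0, 0), c(1, 0, 0))
  cube <- cube_mesh(c(4.5, -0.5, -0.5))  # centered at (5, 0, 0)
  m <- mirror_mesh(cube, pl)
  expect_equal(colMeans(m$vertices), c(-5, 0, 0), tolerance = 1e-12)
  tri <- surface_mesh(rbind(c(0, 1, 2), c(0, 5, 1), c(0, -1, 0)),
                      matrix(1:3, 1))
  expect_equal(mirror_mesh(tri, pl)$vertices, tri$vertices, tolerance = 1e-15)
})

test_that("kabsch recovers exact transforms and the identity", {
  set.seed(7)
  src <- matrix(rnorm(30, sd = 20), 10, 3)
  R <- rotation_about_axis(c(0, 0, 1), 30 * pi / 180)
  tr <- c(1, 2, 3)
  tgt <- src %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
  fit <- kabsch_align(src, tgt)
  expect_lt(max(abs(fit$transform$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - tr)), 1e-9)
  expect_lt(fit$rmsd, 1e-9)

  idfit <- kabsch_align(src, src)
  expect_lt(max(abs(idfit$transform$rotation - diag(3))), 1e-12)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-12)

  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_align(line, line), "collinear")
  expect_error(kabsch_align(src[1:2, ], tgt[1:2, ]), "at least 3")
})

test_that("kabsch under noise: error scales with sigma, small at 0.5 mm", {
  angs <- c()
  rmsds <- list()
  for (seed in 1:40) {
    set.seed(seed)
    src <- matrix(rnorm(60, sd = 30), 20, 3)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, 20 * pi / 180))
    tr <- runif(3, -15, 15)
    for (sigma in c(0.5, 2)) {
      tgt <- src %*% t(R) + matrix(tr, 20, 3, byrow = TRUE) +
        matrix(rnorm(60, sd = sigma), 20, 3)
      fit <- kabsch_align(src, tgt)
      if (sigma == 0.5) {
        angs <- c(angs, rotation_angle(t(fit$transform$rotation) %*% R))
      }
      rmsds[[paste(seed, sigma)]] <- c(sigma, fit$rmsd)
    }
  }
  expect_lt(mean(angs) * 180 / pi, 2)
  rm <- do.call(rbind, rmsds)
  expect_gt(mean(rm[rm[, 1] == 2, 2]), mean(rm[rm[, 1] == 0.5, 2]))  # monotone
})

test_that("apply_transform is a rigid motion with exact inverse", {
  s <- make_phantom("sphere", list(radius = 4), resolution = 1)
  tf <- rigid_transform(rotation_about_axis(c(1, 2, 3), 0.7), c(-3, 8, 1))
  moved <- apply_transform(s, tf)
  e <- s$faces[, 1:2]
  len0 <- sqrt(rowSums((s$vertices[e[, 1], ] - s$vertices[e[, 2], ])^2))
  len1 <- sqrt(rowSums((moved$vertices[e[, 1], ] - moved$vertices[e[, 2], ])^2))
  expect_equal(len1, len0, tolerance = 1e-9)
  back <- apply_transform(moved, invert_transform(tf))
  expect_lt(max(abs(back$vertices - s$vertices)), 1e-12)
  ident <- compose_transform(tf, invert_transform(tf))
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(ident$translation)), 1e-12)
})

test_that("rigid_transform rejects improper rotations", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "det")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("compose_model concatenates and realigns synthetic fractures", {
  a <- cube_mesh(c(0, 0, 0))
  b <- cube_mesh(c(5, 0, 0))
  both <- compose_model(list(list(mesh = a), list(mesh = b)))
  expect_equal(n_vertices(both), 16)
  expect_equal(n_faces(both), 24)
  expect_error(compose_model(list()), "at least one")

  # plane-cut phantom: displaced fragment composed with the inverse
  # transform lands its cut face back on the other fragment's cut face
  tube <- fx_tube_truth()
  pl <- mirror_plane(c(40 * cos(0.8), 40 * sin(0.8), 0),
                     c(-sin(0.8), cos(0.8), 0))
  disp <- rigid_transform(rotation_about_axis(c(0, 0, 1), 0.2), c(4, -2, 6))
  fr <- fracture_phantom(tube, pl, disp)
  reduced <- compose_model(list(
    list(mesh = fr$fragment_a),
    list(mesh = fr$fragment_b, transform = invert_transform(disp))))
  # cut-plane vertices of both fragments coincide after reduction
  on_cut_a <- abs((fr$fragment_a$vertices -
                     matrix(pl$point, n_vertices(fr$fragment_a), 3,
                            byrow = TRUE)) %*% pl$normal) < 1e-9
  vb_back <- transform_points(fr$fragment_b$vertices, invert_transform(disp))
  on_cut_b <- abs((vb_back - matrix(pl$point, nrow(vb_back), 3, byrow = TRUE)) %*%
                    pl$normal) < 1e-9
  a_cut <- fr$fragment_a$vertices[on_cut_a, , drop = FALSE]
  b_cut <- vb_back[on_cut_b, , drop = FALSE]
  expect_gt(nrow(a_cut), 10)
  d <- closest_pairwise(a_cut, b_cut)
  expect_lt(max(d), 1e-9)
})

test_that("landmark reduction recovers ground truth on synthetic fractures", {
  tube <- fx_tube_truth()
  for (seed in 1:5) {
    set.seed(seed)
    ang <- runif(1, 0, 20 * pi / 180)
    disp <- rigid_transform(rotation_about_axis(rnorm(3), ang),
                            runif(3, -15, 15))
    pl <- mirror_plane(c(40 * cos(0.9), 40 * sin(0.9), 0),
                       c(-sin(0.9), cos(0.9), 0))
    fr <- fracture_phantom(tube, pl, disp)
    idx <- round(seq(1, n_vertices(fr$fragment_b), length.out = 6))
    lm_src <- fr$fragment_b$vertices[idx, ]
    lm_tgt <- transform_points(lm_src, invert_transform(disp))
    fit <- kabsch_align(lm_src, lm_tgt)
    inv <- invert_transform(disp)
    expect_lt(rotation_angle(t(fit$transform$rotation) %*% inv$rotation), 1e-6)
    expect_lt(max(abs(fit$transform$translation - inv$translation)), 1e-6)
  }
})

test_that("icp refines a perturbed start back to alignment", {
  s <- make_phantom("sphere", list(radius = 8), resolution = 1.2)
  half <- s
  keep <- s$vertices[s$faces[, 1], 3] > 0  # upper-hemisphere faces
  half$faces <- half$faces[keep, , drop = FALSE]
  tf_true <- rigid_transform(rotation_about_axis(c(0, 1, 0), 0.03),
                             c(0.3, -0.2, 0.1))
  src <- apply_transform(half, tf_true)
  tf <- icp_refine(src, s)
  moved <- apply_transform(src, tf)
  d <- closest_point(s, moved$vertices)$distances
  expect_lt(mean(d), 0.05)
})
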