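test_that("project_anchors: identity on-surface, vertical foot, sphere radius", {
  g <- make_phantom("flat_grid", list(size_x = 50, size_y = 50), resolution = 1)
  on <- rbind(c(-10, 0, 0), c(10, 0, 0))
  expect_equal(project_anchors(g, on), on, tolerance = 1e-12)
  above <- rbind(c(-10, 3, 5), c(10, -2, 5))
  proj <- project_anchors(g, above)
  expect_equal(proj, cbind(above[, 1:2], 0), tolerance = 1e-12)

  s <- make_phantom("sphere", list(radius = 20), resolution = 1)
  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * (20 + runif(10, -2, 2))
  ps <- project_anchors(s, pts)
  expect_equal(sqrt(rowSums(ps^2)), rep(20, nrow(ps)), tolerance = 0.05)

  expect_error(project_anchors(g, rbind(c(0, 0, 1))), "at least 2")
  expect_error(project_anchors(g, rbind(c(0, 0, 1), c(0, 0, 2))),
               "fewer than 2 distinct")
})

test_that("build_path: flat limit, great-circle length, lambda = 0 no-op", {
  g <- make_phantom("flat_grid", list(size_x = 80, size_y = 40), resolution = 1)
  anch <- rbind(c(-30, 0, 0), c(30, 0, 0))
  p <- build_path(g, anch)
  expect_equal(arc_length(p), 60, tolerance = 1e-6)
  expect_true(all(p$on_surface))
  expect_lt(max(abs(p$samples[, 3])), 1e-9)

  s <- fx_sphere100()
  th <- seq(0, pi / 2, by = pi / 6)  # anchors every 30 deg
  anch <- cbind(100 * cos(th), 100 * sin(th), 0)
  pa <- project_anchors(s, anch)
  path <- build_path(s, pa)
  expect_equal(arc_length(path), 100 * pi / 2, tolerance = 0.01)

  pp0 <- path_params(smoothing_lambda = 0)
  p1 <- build_path(g, anch <- rbind(c(-20, -5, 0), c(0, 8, 0), c(20, -5, 0)),
                   pp0)
  # lambda = 0 path equals the projected spline (no smoothing applied):
  # rebuild with zero iterations and compare
  p2 <- build_path(g, anch, path_params(smoothing_lambda = 0.5,
                                        smoothing_iterations = 0))
  expect_equal(p1$samples, p2$samples, tolerance = 1e-14)
})

test_that("surface_path invariants: cumulative lengths and anchor order", {
  s <- fx_sphere100()
  th <- seq(0.2, 1.2, length.out = 5)
  pa <- project_anchors(s, cbind(100 * cos(th), 100 * sin(th), 0))
  path <- build_path(s, pa)
  seg <- sqrt(rowSums(diff(path$samples)^2))
  expect_equal(diff(path$cumulative_length), seg, tolerance = 1e-9)
  expect_true(all(diff(path$anchor_indices) > 0))
  # on-surface samples are on the mesh
  d <- closest_point(s, path$samples[path$on_surface, ])$distances
  expect_lt(max(d), path_params()$projection_tolerance)
})

test_that("build_path is deterministic", {
  s <- fx_sphere100()
  th <- seq(0, 1, length.out = 4)
  pa <- project_anchors(s, cbind(100 * cos(th), 100 * sin(th), 0))
  p1 <- build_path(s, pa)
  p2 <- build_path(s, pa)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$cumulative_length, p2$cumulative_length)
})

test_that("wrap_path bridges a slot with a straight chord", {
  g1 <- make_phantom("flat_grid", list(size_x = 40, size_y = 30),
                     resolution = 1, center = c(-30, 0, 0))
  g2 <- make_phantom("flat_grid", list(size_x = 40, size_y = 30),
                     resolution = 1, center = c(30, 0, 0))
  both <- merge_meshes(list(g1, g2))  # slot: x in (-10, 10)
  anch <- cbind(seq(-45, 45, length.out = 9), 0, 0)
  path <- build_path(both, project_anchors(both, anch))
  expect_gt(sum(!path$on_surface), 0)
  w <- wrap_path(path, both, path_params())
  expect_gt(sum(!w$on_surface), 10)
  bridge <- w$samples[!w$on_surface, , drop = FALSE]
  expect_lt(max(abs(bridge[, 3])), 1e-9)   # straight chord at z = 0
  expect_lt(max(abs(bridge[, 2])), 1e-9)
  # bridge spans roughly the slot width
  expect_equal(diff(range(bridge[, 1])), 20, tolerance = 1.5)
  # identity on fully on-surface paths
  gsolid <- make_phantom("flat_grid", list(size_x = 60, size_y = 30),
                         resolution = 1)
  p2 <- build_path(gsolid, rbind(c(-20, 0, 0), c(20, 0, 0)))
  expect_identical(wrap_path(p2, gsolid, path_params()), p2)
})

test_that("wrap_path rejects paths starting or ending off-surface", {
  p <- surface_path(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                    on_surface = c(FALSE, TRUE, TRUE))
  g <- make_phantom("flat_grid", list(size_x = 10, size_y = 10), resolution = 1)
  expect_error(wrap_path(p, g, path_params()), "start and end")
})

test_that("match_length implements the mid-line crop/lengthen rule", {
  straight <- function(S) {
    surface_path(rbind(c(0, 0, 0), c(S, 0, 0)))
  }
  # S = 50, L = 10: exact multiple, unchanged
  r <- match_length(straight(50), 10)
  expect_equal(r$unit_count, 5L)
  expect_equal(arc_length(r$adjusted_path), 50, tolerance = 1e-9)
  # S = 54: residual 4 < 5 -> crop to 50
  r <- match_length(straight(54), 10)
  expect_equal(r$unit_count, 5L)
  expect_equal(arc_length(r$adjusted_path), 50, tolerance = 1e-9)
  # S = 56: residual 6 >= 5 -> lengthen to 60
  r <- match_length(straight(56), 10)
  expect_equal(r$unit_count, 6L)
  expect_equal(arc_length(r$adjusted_path), 60, tolerance = 1e-9)
  # tie r = L/2 exactly -> lengthen
  r <- match_length(straight(25), 10)
  expect_equal(r$unit_count, 3L)
  # short path still yields one unit
  r <- match_length(straight(3), 10)
  expect_equal(r$unit_count, 1L)
  expect_equal(arc_length(r$adjusted_path), 10, tolerance = 1e-9)
  expect_error(match_length(straight(5), -1), "positive")
})

test_that("match_length extension re-projects onto the bone", {
  s <- fx_sphere100()
  th <- seq(0, 0.56, length.out = 5)  # S ~ 56 mm along the equator
  pa <- project_anchors(s, cbind(100 * cos(th), 100 * sin(th), 0))
  path <- build_path(s, pa)
  r <- match_length(path, 10, s)
  expect_equal(arc_length(r$adjusted_path), r$unit_count * 10,
               tolerance = 1e-6)
  d <- closest_point(s, r$adjusted_path$samples)$distances
  expect_lt(max(d), 0.5)  # extension hugged the sphere
})

test_that("arc_length equals direct segment summation", {
  sq <- surface_path(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(0, 5, 0),
                           c(0, 0, 0)))
  expect_equal(arc_length(sq), 20, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:5) {
    pts <- matrix(rnorm(30), 10, 3)
    p <- surface_path(pts)
    expect_equal(arc_length(p), sum(sqrt(rowSums(diff(pts)^2))),
                 tolerance = 1e-9)
  }
})
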