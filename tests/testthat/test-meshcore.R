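test_that("surface_mesh validates indices and degenerate faces", {
  v <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  expect_s3_class(surface_mesh(v, matrix(c(1, 2, 3), 1)), "surface_mesh")
  expect_error(surface_mesh(v, matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(surface_mesh(v, matrix(c(1, 2, 2), 1)), "repeated")
})

test_that("vertex normals: cube corner, sphere radial, flat grid", {
  cube <- cube_mesh()
  # corner at origin: normalized (-1,-1,-1)/sqrt(3) by symmetry of equal-area
  # incident faces
  n <- vertex_normal(cube, 1)
  expect_equal(abs(n), rep(1 / sqrt(3), 3), tolerance = 1e-12)
  expect_equal(sqrt(sum(n^2)), 1, tolerance = 1e-12)

  s <- make_phantom("sphere", list(radius = 7), resolution = 0.8)
  vn <- vertex_normal(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  ang <- acos(pmin(1, rowSums(vn * radial))) * 180 / pi
  expect_lt(max(ang), 1)

  g <- make_phantom("flat_grid", list(size_x = 10, size_y = 10), resolution = 1)
  interior <- which(abs(g$vertices[, 1]) < 4 & abs(g$vertices[, 2]) < 4)
  vng <- vertex_normal(g)
  expect_equal(vng[interior, , drop = FALSE],
               matrix(rep(c(0, 0, 1), each = length(interior)),
                      ncol = 3), tolerance = 1e-14)
})

test_that("vertex_normal rejects isolated vertices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5))
  m <- surface_mesh(v, matrix(c(1, 2, 3), 1))
  expect_error(vertex_normal(m, 4), "isolated")
})

test_that("closest_point matches analytic sphere distance and vertex hits", {
  s <- make_phantom("sphere", list(radius = 10), resolution = 1)
  cp <- closest_point(s, c(0, 0, 0))
  expect_equal(cp$distance, 10, tolerance = 0.02)  # facet chord error
  # query coincident with a vertex
  cp2 <- closest_point(s, s$vertices[17, ])
  expect_equal(cp2$distance, 0, tolerance = 1e-12)
  # normal is a unit vector, distance equals |query - point|
  q <- c(3, 4, 20)
  cp3 <- closest_point(s, q)
  expect_equal(sqrt(sum(cp3$normal^2)), 1, tolerance = 1e-9)
  expect_equal(cp3$distance, sqrt(sum((q - cp3$point)^2)), tolerance = 1e-9)
})

test_that("closest_point equals the brute-force oracle on random meshes", {
  for (seed in 1:3) {
    m <- random_mesh(500, seed)
    set.seed(seed + 100)
    queries <- matrix(rnorm(3 * 30, sd = 8), ncol = 3)
    res <- closest_point(m, queries)
    for (i in seq_len(nrow(queries))) {
      orc <- oracle_closest(m, queries[i, ])
      expect_equal(res$distances[i], orc$dist, tolerance = 1e-9)
      # face may differ only by an exact tie
      expect_lt(abs(orc$all[res$face_indices[i]] - orc$dist), 1e-9)
    }
  }
})

test_that("min_clearance: analytic gaps, overlap, symmetry, density monotone", {
  c1 <- cube_mesh(c(0, 0, 0))
  c2 <- cube_mesh(c(3, 0, 0))
  expect_equal(min_clearance(c1, c2, 4), 2, tolerance = 1e-12)
  expect_equal(min_clearance(cube_mesh(), cube_mesh(c(0.5, 0.2, 0)), 4), 0)
  s <- make_phantom("sphere", list(radius = 5), resolution = 0.7,
                    center = c(12, 0, 0))
  d_ab <- min_clearance(c1, s, 4)
  d_ba <- min_clearance(s, c1, 4)
  # analytic gap: sphere surface at x = 7 (minus chord sag), cube face at 1
  expect_equal(d_ab, 6, tolerance = 0.05)
  expect_equal(d_ab, d_ba, tolerance = 0.05)
  expect_lte(min_clearance(c1, s, 8), min_clearance(c1, s, 0.5) + 1e-12)
})

test_that("weld merges near-coincident vertices and drops collapsed faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1e-9, 0, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3), c(4, 2, 3)))
  w <- weld(m, tolerance = 1e-6)
  expect_equal(n_vertices(w), 3)
  expect_equal(n_faces(w), 2)  # both faces survive, remapped
  w2 <- weld(surface_mesh(v, rbind(c(1, 4, 2))), tolerance = 1e-6)
  expect_equal(n_faces(w2), 0)  # face collapsed by the weld
})

test_that("repair_orientation makes windings consistent and outward", {
  cube <- cube_mesh()
  scrambled <- cube
  flip <- c(1, 4, 7, 10)
  scrambled$faces[flip, ] <- scrambled$faces[flip, c(1, 3, 2)]
  expect_lt(abs(mesh_volume(scrambled)), 1)  # inconsistent -> wrong volume
  fixed <- repair_orientation(scrambled)
  expect_equal(mesh_volume(fixed), 1, tolerance = 1e-12)
  expect_true(mesh_is_watertight(fixed))
})

test_that("mesh_area and mesh_volume agree with analytic sphere", {
  s <- make_phantom("sphere", list(radius = 10), resolution = 1)
  expect_equal(mesh_area(s), 4 * pi * 100, tolerance = 0.01)
  expect_equal(mesh_volume(s), 4 / 3 * pi * 1000, tolerance = 0.01)
})
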