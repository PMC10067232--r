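test_that("unit spec validation and default catalog", {
  lib <- default_unit_library()
  expect_length(lib, 4)
  expect_setequal(names(lib), c("civic", "depuy_synthes", "zimmer", "inhouse"))
  expect_error(plate_unit_spec(hole_diameter = 12, width = 10), "hole_diameter")
  expect_error(plate_unit_spec(thickness = -1), "thickness")
  expect_error(plate_unit_spec(clearance_threshold = 0.9, standoff = 0.5),
               "clearance_threshold")
})

test_that("unit library JSON round-trip and validation errors", {
  lib <- default_unit_library()
  f <- withr::local_tempfile(fileext = ".json")
  save_unit_library(lib, f)
  back <- load_unit_library(f)
  expect_equal(back, lib)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"broken": {"unit_length": 12, "width": 10}}', bad)
  expect_error(load_unit_library(bad), "broken.*missing")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"x": {"unit_length": 12, "width": 10, "thickness": 2.8,',
                    ' "hole_diameter": 11}}'), bad2)
  expect_error(load_unit_library(bad2), "hole_diameter")
})

test_that("unit_mesh: watertight, analytic volume, exact bounding box", {
  spec <- plate_unit_spec(unit_length = 12, width = 10, thickness = 2.8,
                          hole_diameter = 3.6, hole_segments = 64)
  m <- unit_mesh(spec)
  expect_true(mesh_is_watertight(m))
  analytic <- 12 * 10 * 2.8 - pi * 1.8^2 * 2.8
  expect_equal(mesh_volume(m), analytic, tolerance = 0.01)
  bb <- apply(m$vertices, 2, function(x) diff(range(x)))
  expect_equal(bb, c(12, 10, 2.8), tolerance = 1e-12)
  # degenerate but legal: triangular hole
  m3 <- unit_mesh(plate_unit_spec(hole_segments = 3))
  expect_true(mesh_is_watertight(m3))
})

test_that("compute_frames: flat limit, orthonormality, no flips", {
  g <- make_phantom("flat_grid", list(size_x = 80, size_y = 40), resolution = 1)
  path <- build_path(g, rbind(c(-30, 0, 0), c(30, 0, 0)))
  ml <- match_length(path, 12, g)
  frames <- compute_frames(ml$adjusted_path, g, ml$unit_count, 12)
  for (f in frames) {
    expect_equal(f$normal, c(0, 0, 1), tolerance = 1e-9)
    expect_equal(abs(f$tangent[1]), 1, tolerance = 1e-9)
    # orthonormal right-handed
    expect_lt(abs(sum(f$tangent * f$normal)), 1e-6)
    expect_lt(abs(sum(f$tangent * f$binormal)), 1e-6)
    expect_lt(abs(sum(f$normal * f$binormal)), 1e-6)
    expect_equal(pracma_cross(f$tangent, f$normal), f$binormal,
                 tolerance = 1e-6)
  }
  # chain spacing: consecutive origins one unit length apart
  org <- t(vapply(frames, `[[`, numeric(3), "origin"))
  expect_equal(sqrt(rowSums(diff(org)^2)),
               rep(12, nrow(org) - 1), tolerance = 0.03)
  expect_error(compute_frames(ml$adjusted_path, g, ml$unit_count + 1, 12),
               "match_length")
})

test_that("frame normals never flip along random smooth sphere paths", {
  s <- fx_sphere100()
  set.seed(99)
  for (rep in 1:20) {
    # random great-circle-ish arc
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    th <- seq(0, runif(1, 0.5, 1.5), length.out = 5)
    anch <- 100 * (cos(th) %o% u + sin(th) %o% v)
    path <- build_path(s, project_anchors(s, anch))
    ml <- match_length(path, 12, s)
    frames <- compute_frames(ml$adjusted_path, s, ml$unit_count, 12)
    ns <- t(vapply(frames, `[[`, numeric(3), "normal"))
    if (nrow(ns) > 1) {
      dots <- rowSums(ns[-1, , drop = FALSE] * ns[-nrow(ns), , drop = FALSE])
      expect_gt(min(dots), 0)
    }
  }
})

test_that("resolve_penetration: flat no-op, ridge offset, concave valley", {
  g <- make_phantom("flat_grid", list(size_x = 60, size_y = 40), resolution = 1)
  spec <- plate_unit_spec()
  fr <- unit_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  res <- resolve_penetration(fr, spec, g)
  expect_equal(res$offset, 0)
  expect_equal(res$clearance, 0.5, tolerance = 0.02)

  # 2 mm ridge through the unit footprint forces a lift-off
  rv <- as.matrix(expand.grid(x = c(-1, 1), y = c(-20, 20), z = c(0, 2)))
  rf <- matrix(c(1, 3, 2, 2, 3, 4, 5, 6, 7, 6, 8, 7, 1, 2, 5, 2, 6, 5,
                 3, 7, 4, 4, 7, 8, 1, 5, 3, 3, 5, 7, 2, 4, 6, 4, 8, 6),
               ncol = 3, byrow = TRUE)
  ridge <- repair_orientation(surface_mesh(rv, rf))
  bone <- merge_meshes(list(g, ridge))
  res2 <- resolve_penetration(fr, spec, bone)
  expect_gte(res2$offset, 2 - spec$standoff + spec$clearance_threshold - 2e-3)
  expect_gte(res2$clearance, spec$clearance_threshold - 1e-3)

  # concave valley: open parabolic sheet z = x^2 / 200, frame at the bottom
  valley <- make_phantom("flat_grid", list(size_x = 60, size_y = 40),
                         resolution = 1)
  valley$vertices[, 3] <- valley$vertices[, 1]^2 / 200
  frv <- unit_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  res3 <- resolve_penetration(frv, spec, valley)
  expect_equal(res3$offset, 0)
  expect_gte(res3$clearance, spec$clearance_threshold)
})

test_that("assemble_template poses units safely along an arc", {
  s <- fx_sphere100()
  th <- seq(0, 0.9, length.out = 6)
  path <- build_path(s, project_anchors(s, cbind(100 * cos(th),
                                                 100 * sin(th), 0)))
  ml <- match_length(path, 12, s)
  spec <- plate_unit_spec()
  frames <- compute_frames(ml$adjusted_path, s, ml$unit_count, 12)
  tpl <- assemble_template(frames, spec, s)
  expect_s3_class(tpl, "plate_template")
  expect_equal(length(tpl$frames), ml$unit_count)
  expect_equal(n_vertices(tpl$mesh),
               ml$unit_count * n_vertices(unit_mesh(spec)))
  expect_gte(min(tpl$clearances), spec$clearance_threshold - 1e-3)
  # on a sphere the underside center sits at radius + standoff
  for (i in seq_along(tpl$frames)) {
    f <- tpl$frames[[i]]
    bottom <- f$origin + (spec$standoff + tpl$offsets[i]) * f$normal
    expect_equal(sqrt(sum(bottom^2)), 100 + spec$standoff, tolerance = 0.2)
  }
  # independent clearance verification
  expect_gte(min_clearance(tpl$mesh, s, 2),
             spec$clearance_threshold - 1e-3)
})

test_that("export_template writes STL + sidecar that reload faithfully", {
  g <- make_phantom("flat_grid", list(size_x = 60, size_y = 40), resolution = 1)
  path <- build_path(g, rbind(c(-20, 0, 0), c(20, 0, 0)))
  ml <- match_length(path, 12, g)
  spec <- plate_unit_spec()
  frames <- compute_frames(ml$adjusted_path, g, ml$unit_count, 12)
  tpl <- assemble_template(frames, spec, g)
  f <- withr::local_tempfile(fileext = ".stl")
  files <- export_template(tpl, f)
  m <- read_stl(f)
  expect_equal(n_faces(m), n_faces(tpl$mesh))
  expect_equal(file.info(f)$size, 84 + 50 * n_faces(tpl$mesh))
  side <- jsonlite::read_json(files[["sidecar"]], simplifyVector = TRUE)
  expect_equal(length(side$frames$origin[[1]]), 3)
  fr1 <- side$frames
  expect_equal(unlist(fr1$origin[1]), tpl$frames[[1]]$origin,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unlist(fr1$normal[1]), tpl$frames[[1]]$normal,
               tolerance = 1e-12, ignore_attr = TRUE)
})
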