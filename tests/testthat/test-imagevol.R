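test_that("NRRD round-trip preserves intensities and geometry", {
  set.seed(5)
  arr <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  vol <- voxel_volume(arr, spacing = c(1, 1, 3), origin = c(-2, 0, 7))
  for (enc in c("raw", "ascii")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_nrrd(vol, f, encoding = enc)
    back <- read_nrrd(f)
    expect_equal(back$intensities, arr,
                 tolerance = if (enc == "raw") 0 else 1e-12)
    expect_equal(back$spacing, vol$spacing)
    expect_equal(back$origin, vol$origin)
  }
})

test_that("load_volume reads the shipped short/ascii fixture", {
  f <- system.file("extdata", "tiny_short.nrrd", package = "plateforge")
  vol <- load_volume(f)
  expect_equal(dim(vol$intensities), c(4, 3, 2))
  expect_equal(vol$spacing, c(0.8, 0.8, 3))
  expect_equal(sum(vol$intensities == 1200), 6)
  expect_error(load_volume(tempdir()), "DICOM")
})

test_that("threshold_segment: inclusive bounds, open windows, monotonicity", {
  arr <- array(c(-100, 300, 500, 1200), c(4, 1, 1))
  vol <- voxel_volume(arr)
  expect_equal(as.vector(threshold_segment(vol, 300, 500)$labels),
               c(0L, 1L, 1L, 0L))
  expect_equal(sum(threshold_segment(vol, 2000)$labels), 0)
  expect_equal(sum(threshold_segment(vol, -Inf, Inf)$labels), 4)
  expect_error(threshold_segment(vol, 10, 5), "must be <=")
  # monotone in the window on a random volume
  set.seed(1)
  v2 <- voxel_volume(array(runif(1000, -200, 1500), c(10, 10, 10)))
  narrow <- threshold_segment(v2, 300, 800)$labels
  wide <- threshold_segment(v2, 200, 900)$labels
  expect_true(all(wide[narrow == 1L] == 1L))
})

test_that("threshold captures the analytic sphere volume", {
  s <- make_phantom("sphere", list(radius = 10), resolution = 1)
  vol <- voxelize_phantom(s, spacing = c(0.5, 0.5, 0.5))
  mask <- threshold_segment(vol, 300)
  vox_vol <- sum(mask$labels) * prod(vol$spacing)
  expect_equal(vox_vol, 4 / 3 * pi * 1000, tolerance = 0.05)
})

test_that("split_components: ordering, connectivity semantics, flood-fill oracle", {
  # two spheres, the larger must get label 1
  s1 <- make_phantom("sphere", list(radius = 8), resolution = 1)
  s2 <- make_phantom("sphere", list(radius = 4), resolution = 1,
                     center = c(25, 0, 0))
  vol <- voxelize_phantom(merge_meshes(list(s1, s2)), spacing = c(1, 1, 1))
  comps <- split_components(threshold_segment(vol, 300))
  expect_equal(max(comps$labels), 2)
  expect_gt(sum(comps$labels == 1L), sum(comps$labels == 2L))

  # diagonal voxels: separate under 6, joined under 26
  arr <- array(0L, c(2, 2, 2))
  arr[1, 1, 1] <- 1L
  arr[2, 2, 2] <- 1L
  lm <- label_map(arr)
  expect_equal(max(split_components(lm, 6)$labels), 2)
  expect_equal(max(split_components(lm, 26)$labels), 1)

  # random masks vs independent flood fill
  for (seed in 1:4) {
    set.seed(seed)
    mask <- array(runif(12^3) < 0.25, c(12, 12, 12))
    lm <- label_map(array(as.integer(mask), dim(mask)))
    for (conn in c(6, 26)) {
      got <- split_components(lm, conn)$labels
      want <- oracle_flood_fill(mask, conn)
      expect_equal(max(got), max(want))
      # identical partition: same-label sets must coincide
      expect_equal(length(unique(paste(got[mask], want[mask]))), max(want))
      expect_true(all((got > 0) == mask))
    }
  }
})

test_that("erase_labels renumbers contiguously and validates ids", {
  arr <- array(0L, c(6, 1, 1))
  arr[1:2] <- 1L; arr[3:4] <- 2L; arr[5:6] <- 3L
  lm <- label_map(arr)
  out <- erase_labels(lm, 2)
  expect_equal(sort(unique(as.vector(out$labels))), c(0L, 1L, 2L))
  expect_equal(as.vector(out$labels)[5:6], c(2L, 2L))  # old 3 -> new 2
  expect_equal(sum(erase_labels(lm, 1:3)$labels), 0)
  expect_equal(erase_labels(lm, integer(0))$labels, lm$labels)
  expect_error(erase_labels(lm, 9), "not present.*9")
})

test_that("extract_surface: watertight, analytic area/volume, inside bbox", {
  s <- make_phantom("sphere", list(radius = 10), resolution = 1)
  vol <- voxelize_phantom(s, spacing = c(0.5, 0.5, 0.5))
  comps <- split_components(threshold_segment(vol, 300))
  surf <- extract_surface(comps, 1)
  expect_true(mesh_is_watertight(surf))
  expect_equal(mesh_area(surf), 4 * pi * 100, tolerance = 0.05)
  expect_equal(mesh_volume(surf), 4 / 3 * pi * 1000, tolerance = 0.05)
  # vertices within the dilated voxel bounding box
  expect_true(all(abs(surf$vertices) <= 10 + 2 * 0.5 + 1e-9))
  expect_error(extract_surface(comps, 7), "not present")
})

test_that("single-voxel label extracts as a closed surface", {
  arr <- array(0L, c(5, 5, 5))
  arr[3, 3, 3] <- 1L
  surf <- extract_surface(label_map(arr), 1, anti_alias_sigma = 0,
                          smooth_iterations = 0)
  expect_true(mesh_is_watertight(surf))
  expect_gt(mesh_volume(surf), 0)
})
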