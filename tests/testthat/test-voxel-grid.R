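test_that("voxel_grid validates its invariants", {
  expect_error(voxel_grid(matrix(0, 2, 2), c(1, 1, 1)), "rank-3")
  expect_error(voxel_grid(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  g <- voxel_grid(array(1, c(2, 3, 4)), c(5, 1.105, 1.105), c(-1, 0, 2))
  expect_identical(dim(g$values), c(2L, 3L, 4L))
  expect_equal(voxel_volume_mL(g), 5 * 1.105 * 1.105 / 1000)
})

test_that("NIfTI round-trip preserves values, spacing and origin", {
  set.seed(1)
  g <- voxel_grid(array(runif(60), c(3, 4, 5)),
                  spacing = c(5, 1.105, 1.105), origin = c(-10, -20, 7.5))
  path <- tempfile(fileext = ".nii.gz")
  write_grid_nifti(g, path)
  g2 <- read_grid_nifti(path)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
})

test_that("Gaussian blur conserves total signal away from edges and is linear", {
  geom <- cube_geom(24)
  v <- sphere_voi(60, geom)
  g <- voxel_grid(v$mask * 500, geom$spacing, geom$origin)
  b <- blur_grid(g, 12)
  expect_equal(sum(b$values), sum(g$values), tolerance = 1e-6)
  b2 <- blur_grid(voxel_grid(g$values * 3.5, g$spacing, g$origin), 12)
  expect_equal(b2$values, 3.5 * b$values, tolerance = 1e-12)
  # FWHM 0 is the identity
  expect_identical(blur_grid(g, 0)$values, g$values)
  expect_error(blur_grid(g, -1), ">= 0")
})
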