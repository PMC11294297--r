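ct_geom <- default_ct_geometry(c(90, 90, 90))
spect_geom <- default_spect_geometry(ct_geom)

test_that("resampling to the same geometry is the identity", {
  v <- sphere_voi(40, ct_geom)
  r <- resample_voi(v, ct_geom, "fractional")
  expect_identical(r$mask, v$mask)
})

test_that("a single 1 mm voxel resampled to the SPECT grid keeps its volume", {
  src <- grid_geometry(c(9, 9, 9), c(1, 1, 1), c(-4, -4, -4))
  m <- array(0, c(9, 9, 9)); m[5, 5, 5] <- 1
  v <- voi(m, src, "px@B_L")
  tg <- grid_geometry(c(3, 3, 3), rep(4.42, 3), rep(-4.42, 3))
  r <- resample_voi(v, tg, "fractional")
  # the voxel lies entirely inside the central target voxel
  expect_equal(max(r$mask), (1 / 4.42)^3, tolerance = 1e-12)
  expect_equal(sum(r$mask), (1 / 4.42)^3, tolerance = 1e-12)
})

test_that("fractional CT-to-SPECT resampling conserves sphere volume", {
  v <- sphere_voi(4 / 3 * pi * 30^3 / 1000, ct_geom)  # 30 mm radius
  r <- resample_voi(v, spect_geom, "fractional")
  expect_equal(voi_volume_mL(r), voi_volume_mL(v), tolerance = 1e-10)
  # and the rasterised CT volume is itself within 1% of the analytic volume
  expect_lt(abs(voi_volume_mL(v) - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.01)
})

test_that("resampling a VOI outside the target grid errors", {
  v <- sphere_voi(10, ct_geom)
  far <- grid_geometry(c(8, 8, 8), rep(4.42, 3), c(500, 500, 500))
  expect_error(resample_voi(v, far), "outside")
})

test_that("propagation copies the mask bit-identically to every tag", {
  v <- sphere_voi(35, ct_geom, "kidney_L@D7")
  one <- propagate_voi(v, "D7")
  expect_identical(one$D7$mask, v$mask)
  four <- propagate_voi(v, c("D0", "D1", "D2", "D7"))
  expect_length(four, 4)
  for (tag in names(four)) {
    expect_identical(four[[tag]]$mask, v$mask)
    expect_identical(voi_volume_mL(four[[tag]]), voi_volume_mL(v))
    expect_identical(four[[tag]]$label, paste0("kidney_L@", tag))
  }
  expect_error(propagate_voi(v, character(0)), "non-empty")
})

test_that("alignment finds a known displacement and honours tie-breaks", {
  geom <- cube_geom(20)
  v <- sphere_voi(50, geom)
  # hot sphere displaced by exactly +2 voxels along x
  img_mask <- sphere_voi(50, geom, center = c(0, 0, 2 * geom$spacing[3]))
  img <- voxel_grid(img_mask$mask * 100, geom$spacing, geom$origin)
  a <- align_voi(img, v, 3)
  expect_identical(attr(a, "shift"), c(0L, 0L, 2L))
  # independent exhaustive oracle over the 7^3 shift grid
  best <- NULL
  for (dz in -3:3) for (dy in -3:3) for (dx in -3:3) {
    sh <- renaldosim:::shift_voi(v, c(dz, dy, dx))
    sc <- sum(img$values * sh$mask)
    if (is.null(best) || sc > best$sc) best <- list(sc = sc, s = c(dz, dy, dx))
  }
  expect_identical(attr(a, "shift"), as.integer(best$s))
  # uniform image: all shifts tie, smallest magnitude wins
  u <- voxel_grid(array(7, geom$dim), geom$spacing, geom$origin)
  expect_identical(attr(align_voi(u, v, 2), "shift"), c(0L, 0L, 0L))
  # zero search radius returns the input unchanged
  a0 <- align_voi(img, v, 0)
  expect_identical(a0$mask, v$mask)
})

test_that("mean concentration is a mask-weighted mean", {
  geom <- cube_geom(6)
  vals <- array(0, geom$dim)
  m <- array(0, geom$dim)
  m[2, 2, 2] <- 1; m[3, 3, 3] <- 1
  vals[2, 2, 2] <- 10; vals[3, 3, 3] <- 30
  img <- voxel_grid(vals, geom$spacing, geom$origin)
  v <- voi(m, geom, "v@D0")
  expect_equal(mean_concentration(img, v), 20)
  const <- voxel_grid(array(3.7, geom$dim), geom$spacing, geom$origin)
  expect_equal(mean_concentration(const, v), 3.7)
  zero <- voxel_grid(array(0, geom$dim), geom$spacing, geom$origin)
  expect_equal(mean_concentration(zero, v), 0)
  expect_error(mean_concentration(img, voi(array(0, geom$dim), geom, "e@D0")),
               "zero-volume")
})

test_that("mean concentration is invariant under a common rigid shift", {
  geom <- cube_geom(16)
  set.seed(3)
  img <- voxel_grid(array(runif(prod(geom$dim)), geom$dim),
                    geom$spacing, geom$origin)
  v <- sphere_voi(25, geom)
  ref <- mean_concentration(img, v)
  for (sh in list(c(1, 0, 0), c(0, -2, 1), c(2, 2, 2))) {
    vs <- renaldosim:::shift_voi(v, sh)
    # shift the image identically (same translation operator on the values)
    gi <- renaldosim:::shift_voi(voi(array(0, geom$dim), geom, "t@D0"), sh)
    imgs <- voxel_grid(renaldosim:::shift_voi(
      voi(img$values / max(img$values), geom, "i@D0"), sh)$mask *
        max(img$values), geom$spacing, geom$origin)
    expect_equal(mean_concentration(imgs, vs), ref, tolerance = 1e-12)
  }
})

test_that("an interior VOI on a blurred uniform object reads higher", {
  geom <- cube_geom(28)
  full <- sphere_voi(130, geom)
  interior <- sphere_voi(80, geom)
  img <- blur_grid(voxel_grid(full$mask * 1000, geom$spacing, geom$origin), 12)
  expect_gt(mean_concentration(img, interior), mean_concentration(img, full))
  # holds for any positive PSF width
  for (f in c(4, 8, 16)) {
    b <- blur_grid(voxel_grid(full$mask * 1000, geom$spacing, geom$origin), f)
    expect_gte(mean_concentration(b, interior), mean_concentration(b, full))
  }
})
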