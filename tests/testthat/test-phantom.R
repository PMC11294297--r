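test_that("default volume multipliers encode the observed kidney swelling", {
  m <- default_volume_multipliers()
  expect_equal(m[["B_L"]], 1.0)
  expect_equal(m[["D0"]], 1.0877)
  expect_equal(m[["D1"]], 1.1007)
  expect_equal(m[["D2"]], 1.0110)
  expect_equal(m[["D7"]], 1.0110)
  s <- default_volume_multipliers("spleen")
  expect_true(all(s == 1.0))
})

test_that("rasterised organ volumes hit the target within half a voxel", {
  geom <- default_ct_geometry(c(150, 120, 120))
  half_vox <- voxel_volume_mL(geom) / 2
  for (shape in c("ellipsoid", "bean")) {
    org <- organ_spec("kidney_L", 130.6, shape = shape)
    for (tag in c("B_L", "D0", "D1")) {
      ph <- make_phantom(list(org), tag, geom)
      target <- 130.6 * default_volume_multipliers()[[tag]]
      expect_lt(abs(ph$volumes_mL[["kidney_L"]] - target), half_vox + 1e-9)
    }
  }
  # multiplier scaling is definitional
  org100 <- organ_spec("k", 100, volume_multipliers = c(D1 = 1.1007))
  ph <- make_phantom(list(org100), "D1", geom)
  expect_equal(ph$volumes_mL[["k"]], 110.07, tolerance = half_vox / 100)
})

test_that("overlapping organs error, near-touching disjoint organs do not", {
  geom <- default_ct_geometry(c(150, 150, 200))
  a <- organ_spec("a", 100, shape = "ellipsoid", center_mm = c(0, 0, -33))
  b <- organ_spec("b", 100, shape = "ellipsoid", center_mm = c(0, 0, 33))
  ph <- make_phantom(list(a, b), "B_L", geom)
  expect_setequal(names(ph$vois), c("a", "b"))
  expect_equal(sum(ph$labels$values == 1) + sum(ph$labels$values == 2),
               sum(ph$labels$values > 0))
  b2 <- organ_spec("b", 100, shape = "ellipsoid", center_mm = c(0, 0, 10))
  expect_error(make_phantom(list(a, b2), "B_L", geom), "collision")
})

test_that("true concentrations follow the kinetics and dilution mechanism", {
  tr_c <- kinetics_truth(2000, 1000, 0.01, 0.05, 0.5,
                         mode = "concentration_primary")
  org <- organ_spec("k", 100, volume_multipliers = c(B_L = 1, D1 = 1.1))
  expect_equal(true_concentration(tr_c, org, 0), 0)
  expect_equal(true_concentration(tr_c, org, 24),
               2000 * exp(-0.24) + 1000 * exp(-1.2) - 3000 * exp(-12),
               tolerance = 1e-12)
  tr_a <- kinetics_truth(2000, 1000, 0.01, 0.05, 0.5)
  # with constant volume, activity mode is concentration mode divided by V
  expect_equal(true_concentration(tr_a, org, 24, tag = "B_L"),
               true_concentration(tr_c, org, 24) / 100, tolerance = 1e-12)
  # swelling dilutes
  expect_lt(true_concentration(tr_a, org, 24, tag = "D1"),
            true_concentration(tr_a, org, 24, tag = "B_L"))
})

test_that("SPECT rendering conserves activity and is linear", {
  geom <- default_ct_geometry(c(200, 180, 180))
  org <- organ_spec("k", 130.6, shape = "ellipsoid")
  ph <- make_phantom(list(org), "B_L", geom)
  acq <- acquisition_spec(psf_fwhm_mm = 12)
  img <- render_spect(ph$labels, 1000, acq)
  truth <- 1000 * ph$volumes_mL[["k"]]
  expect_equal(sum(img$values) * voxel_volume_mL(img), truth,
               tolerance = 1e-3 * truth)
  # zero concentration renders a zero image
  img0 <- render_spect(ph$labels, 0, acq)
  expect_true(all(img0$values == 0))
  # FWHM 0 equals the plain volume-weighted downsampling
  acq0 <- acquisition_spec(psf_fwhm_mm = 0)
  imgd <- render_spect(ph$labels, 1000, acq0)
  sg <- default_spect_geometry(geom)
  painted <- array(0, geom$dim); painted[ph$labels$values == 1] <- 1000
  direct <- renaldosim:::resample_field(painted, geom, sg)
  expect_equal(imgd$values, direct, tolerance = 1e-12)
  # linearity in concentration
  img3 <- render_spect(ph$labels, 3000, acq)
  expect_equal(img3$values, 3 * img$values, tolerance = 1e-9)
})

test_that("Poisson noise is seed-reproducible and seed-sensitive", {
  geom <- default_ct_geometry(c(120, 100, 100))
  org <- organ_spec("k", 80, shape = "ellipsoid")
  ph <- make_phantom(list(org), "B_L", geom)
  acq <- acquisition_spec(psf_fwhm_mm = 12, noise = "poisson",
                          counts_per_Bq_mL_voxel = 1e-3, seed = 99L)
  i1 <- render_spect(ph$labels, 3e5, acq)
  i2 <- render_spect(ph$labels, 3e5, acq)
  expect_identical(i1$values, i2$values)
  i3 <- render_spect(ph$labels, 3e5, acq, rng = 100L)
  expect_false(identical(i1$values, i3$values))
})

test_that("volume time-courses round-trip through the agreement analysis", {
  geom <- default_ct_geometry(c(150, 120, 120))
  set.seed(5)
  rows <- list()
  for (s in 1:3) {
    base <- runif(2, 90, 180)
    for (k in 1:2) {
      org <- organ_spec(paste0("kidney_", k), base[k],
                        center_mm = runif(3, -2, 2))
      for (tag in c("B_L", "D0", "D1", "D2", "D7")) {
        ph <- make_phantom(list(org), tag, geom)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, organ = org$name, tag = tag,
          volume_mL = unname(ph$volumes_mL))
      }
    }
  }
  va <- volume_change_analysis(do.call(rbind, rows))
  mult <- default_volume_multipliers()
  for (tag in c("D0", "D1", "D2", "D7")) {
    got <- va$bias_pct[va$organ_class == "kidney" & va$tag == tag]
    expect_equal(got, 100 * (mult[[tag]] - 1), tolerance = 0.05)
  }
})
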