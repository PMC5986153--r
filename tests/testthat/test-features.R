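flat_volume <- function(fill = 100, d = 40, w = 20, nb = 2,
                        vox = c(3.9, 11.6, 120)) {
  oct_volume(array(fill, dim = c(d, w, nb)), vox)
}

flat_boundaries <- function(depths, w = 20, nb = 2, vox = c(3.9, 11.6, 120)) {
  pos <- array(rep(depths, w * nb), dim = c(12, w, nb),
               dimnames = list(BOUNDARY_ORDER, NULL, NULL))
  boundary_set(pos, vox)
}

test_that("layer mean intensity averages the half-open band", {
  depths <- seq(2, 35, by = 3)
  vol <- flat_volume(100)
  bs <- flat_boundaries(depths)
  expect_equal(layer_mean_intensity(vol, bs, "RNFL"), 100)

  # band of two rows valued 80 and 120
  vol2 <- flat_volume(0, d = 10)
  vol2$data[5, , ] <- 80; vol2$data[6, , ] <- 120
  bs2 <- flat_boundaries(c(1, 2, 3, 3, 3, 3, 3, 3, 3, 3, 4, 6), w = 20)
  expect_equal(layer_mean_intensity(vol2, bs2, c("IZ-RPE", "RBC")), 100)

  expect_error(layer_mean_intensity(vol, flat_boundaries(rep(5, 12)), "RNFL"),
               "empty")

  # phantom band with generative mean, no noise
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 0))
  expect_equal(layer_mean_intensity(ph$volume, ph$truth$boundaries, "RNFL"),
               ph$truth$spec$layer_profile$intensity[1])
})

test_that("HIS detection thresholds on the pooled RNFL/RPE mean and gates space", {
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 0))
  m0 <- detect_his(ph$volume, ph$truth$boundaries)
  expect_equal(sum(m0$mask), 0)

  spec <- tiny_phantom_spec(noise_sd = 0, his_spots = list(
    list(bscan = 1, row = 125, col = 40, radius = 2, intensity = 210)))
  ph2 <- generate_phantom(spec)
  m <- detect_his(ph2$volume, ph2$truth$boundaries)
  expect_equal(m$mask, ph2$truth$his_mask$mask)
  expect_gt(sum(m$mask), 0)

  # bright pixels inside the RNFL band only are not HIS
  ph3 <- generate_phantom(tiny_phantom_spec(noise_sd = 0))
  ph3$volume$data[62:64, 10:12, 1] <- 255    # inside RNFL
  expect_equal(sum(detect_his(ph3$volume, ph3$truth$boundaries)$mask), 0)
})

test_that("drusen detection finds confirmed detachments and applies the ratio gate", {
  # flat thickness profile: no candidates
  ph0 <- generate_phantom(tiny_phantom_spec(noise_sd = 0))
  expect_equal(sum(detect_drusen(ph0$volume, ph0$truth$boundaries)$mask), 0)

  # bright RPE over dark interior: volume within 15% of ground truth
  spec <- tiny_phantom_spec(noise_sd = 0, drusen_bumps = list(
    list(bscans = 0:2, center = 60, radius = 14, height = 16, intensity = 65)))
  ph <- generate_phantom(spec)
  m <- detect_drusen(ph$volume, ph$truth$boundaries)
  gtv <- mask_volume(ph$truth$drusen_mask)
  expect_lt(abs(mask_volume(m) - gtv) / gtv, 0.15)

  # same geometry, interior as bright as the RPE: ratio 1.0, rejected
  spec2 <- tiny_phantom_spec(noise_sd = 0, drusen_bumps = list(
    list(bscans = 0:2, center = 60, radius = 14, height = 16, intensity = 200)))
  ph2 <- generate_phantom(spec2)
  expect_equal(sum(detect_drusen(ph2$volume, ph2$truth$boundaries)$mask), 0)
})

test_that("mask volume is count times voxel volume", {
  vox <- c(3.9, 11.6, 120)
  empty <- oct_mask(array(FALSE, c(4, 4, 2)), "HIS", vox)
  expect_equal(mask_volume(empty), 0)
  m <- array(FALSE, c(20, 25, 2)); m[seq_len(1000)] <- TRUE
  expect_equal(mask_volume(oct_mask(m, "drusen", vox)), 1000 * 5.4288e-6)
})

test_that("thickness profiles and statistics match their definitions", {
  bs <- flat_boundaries(c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 25, 32))
  # parallel flat boundaries 30 px apart at 3.9 um/px: uniform 117 um
  t1 <- thickness_profile(bs, "ILM-RNFL", "RBC", sigma = 3)
  expect_equal(as.numeric(t1), rep(30 * 3.9, length(t1)))

  # sigma = 0 returns the raw differences
  pos <- bs$positions
  pos["RBC", , ] <- 32 + matrix(seq(0, 5, length.out = 20), 20, 2)
  bs2 <- boundary_set(pos, bs$voxel_dims)
  t0 <- thickness_profile(bs2, "ILM-RNFL", "RBC", sigma = 0)
  expect_equal(as.numeric(t0), as.numeric((pos["RBC", , ] - 2) * 3.9))

  # smoothing matches an independent discrete convolution
  t2 <- thickness_profile(bs2, "ILM-RNFL", "RBC", sigma = 2)
  expect_equal(unclass(t2), oracle_gauss2d(unclass(t0), 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # crossing boundaries clamp at zero with a warning
  pos2 <- bs$positions; pos2["RBC", 1, 1] <- 0
  expect_warning(tp <- thickness_profile(boundary_set(pos2, bs$voxel_dims),
                                         "ILM-RNFL", "RBC", sigma = 0),
                 "clamped")
  expect_equal(tp[1, 1], 0)

  expect_equal(thickness_stats(matrix(5, 3, 3)), c(mean = 5, p70 = 5))
  # values 1..10: mean 5.5, h = 9*0.7 + 1 = 7.3 -> p70 = 7.3
  expect_equal(thickness_stats(matrix(1:10, 2)), c(mean = 5.5, p70 = 7.3))
  expect_equal(thickness_stats(matrix(rep(c(0, 100), each = 50)))[["mean"]], 50)
})

test_that("extract_features populates the ten fields with the expected signs", {
  cp <- default_class_params(noise_sd = 0)

  ph <- generate_phantom(cp$normal$template)
  fv <- extract_features(ph$volume, ph$truth$boundaries)
  expect_named(fv, octretina:::FEATURE_NAMES, ignore.order = FALSE)
  expect_equal(unname(fv[c("his_volume_mm3", "drusen_volume_mm3",
                           "curviness_mzez", "curviness_oplonl")]),
               rep(0, 4))
  lp <- cp$normal$template$layer_profile
  expect_equal(unname(fv["retina_mean_um"]),
               (lp$depth[12] - lp$depth[1]) * 3.9)
  expect_equal(unname(fv["rpe_p70_um"]), (lp$depth[12] - lp$depth[11]) * 3.9)

  amd <- generate_phantom(cp$AMD$template)
  fva <- extract_features(amd$volume, amd$truth$boundaries)
  expect_gt(fva[["drusen_volume_mm3"]], 0)
  expect_gt(fva[["curviness_mzez"]], 0)
  expect_equal(fva[["his_volume_mm3"]], 0)

  # determinism
  fva2 <- extract_features(amd$volume, amd$truth$boundaries)
  expect_identical(unclass(fva), unclass(fva2))
})
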