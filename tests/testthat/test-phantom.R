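test_that("phantom generation is deterministic and respects the null world", {
  spec <- tiny_phantom_spec(noise_sd = 6, seed = 123)
  a <- generate_phantom(spec); b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$boundaries$positions, b$truth$boundaries$positions)

  # no pathology, no noise: piecewise-constant B-scans, empty masks
  clean <- generate_phantom(tiny_phantom_spec(noise_sd = 0))
  expect_equal(sum(clean$truth$drusen_mask$mask), 0)
  expect_equal(sum(clean$truth$his_mask$mask), 0)
  lp <- clean$truth$spec$layer_profile
  img <- clean$volume$data[, , 2]
  expect_true(all(img %in% c(clean$truth$spec$vitreous_intensity, lp$intensity)))
  # every pixel equals its generative layer mean
  expect_equal(unique(img[lp$depth[1] + 1, ]), lp$intensity[1])   # RNFL row
  expect_equal(unique(img[1, ]), clean$truth$spec$vitreous_intensity)
})

test_that("drusen bump rasterisation matches a brute-force rasteriser", {
  # semicircular bump: radius 5 px, height 5 px (semicircle), one B-scan
  spec <- phantom_spec(n_bscans = 1, noise_sd = 0, drusen_bumps = list(
    list(bscans = 0, center = 60, radius = 5, height = 5, intensity = 65)))
  ph <- generate_phantom(spec)
  expected <- oracle_bump_count(256, 128, baseline = 200, center = 60,
                                radius = 5, height = 5)
  expect_equal(sum(ph$truth$drusen_mask$mask), expected)

  # a taller semi-elliptic bump
  spec2 <- phantom_spec(n_bscans = 2, noise_sd = 0, drusen_bumps = list(
    list(bscans = 0:1, center = 40, radius = 9, height = 14, intensity = 65)))
  ph2 <- generate_phantom(spec2)
  expect_equal(sum(ph2$truth$drusen_mask$mask),
               2 * oracle_bump_count(256, 128, 200, 40, 9, 14))
  # recorded volume equals count x voxel volume exactly
  expect_equal(mask_volume(ph2$truth$drusen_mask),
               sum(ph2$truth$drusen_mask$mask) * prod(spec2$voxel_dims) / 1e9)
})

test_that("ground-truth boundaries never cross, even under deformation", {
  spec <- phantom_spec(n_bscans = 3, noise_sd = 0,
    drusen_bumps = list(list(bscans = 0:2, center = 50, radius = 12,
                             height = 18, intensity = 65)),
    boundary_waves = list(list(boundary = "OPL-ONL", amplitude = 6,
                               period = 30, phase = 1)))
  ph <- generate_phantom(spec)
  expect_true(boundaries_ordered(ph$truth$boundaries, tol = 0))
})

test_that("invalid geometry is rejected with the offending element named", {
  expect_error(phantom_spec(drusen_bumps = list(
    list(bscans = 0, center = 2, radius = 5, height = 5, intensity = 65))),
    "bump 1")
  expect_error(phantom_spec(his_spots = list(
    list(bscan = 50, row = 120, col = 40, radius = 2, intensity = 200))),
    "spot 1")
  bad_lp <- default_layer_profile(); bad_lp$depth[5] <- bad_lp$depth[4]
  expect_error(phantom_spec(layer_profile = bad_lp), "strictly increasing")
})

test_that("phantom cohorts conserve counts and honour zero jitter", {
  cp <- default_class_params(noise_sd = 0)
  coh <- phantom_cohort(1, cp, seed = 5, jitter_scale = 0)
  labs <- vapply(coh, function(v) v$truth$label, character(1))
  expect_equal(labs, c("normal", "AMD", "DME"))
  # zero jitter: identical to the class templates (up to the noise seed,
  # which is irrelevant at noise_sd = 0)
  for (i in 1:3) {
    tmpl <- cp[[labs[i]]]$template
    ref <- generate_phantom(tmpl, label = labs[i])
    expect_identical(coh[[i]]$volume$data, ref$volume$data, label = labs[i])
  }
  # normal volumes carry no pathology
  expect_equal(sum(coh[[1]]$truth$drusen_mask$mask), 0)
  expect_equal(sum(coh[[1]]$truth$his_mask$mask), 0)

  coh2 <- phantom_cohort(2, cp, seed = 5)
  expect_equal(unname(table(vapply(coh2, function(v) v$truth$label,
                                   character(1)))[c("normal", "AMD", "DME")]),
               rep(2L, 3), ignore_attr = TRUE)
  expect_s3_class(attr(coh2, "provenance"), "data.frame")
  expect_error(phantom_cohort(1, list()), "at least one class")
})
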