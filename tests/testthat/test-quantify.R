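test_that("diameter stenosis recovers the construction value on ground truth", {
  ph50 <- make_vessel_phantom(small_spec(50))
  sl <- phantom_slice_ranges(ph50$truth)
  m <- measure_diameter_stenosis(ph50$volume, reference_slices = sl$reference,
                                 lesion_slices = sl$lesion)
  expect_lt(abs(m - 50), 3)
  # plaque-free vessel measures ~0
  ph0 <- make_vessel_phantom(small_spec(0))
  m0 <- measure_diameter_stenosis(ph0$volume, reference_slices = sl$reference,
                                  lesion_slices = sl$lesion)
  expect_lt(m0, 3)
  # blooming overestimates
  bl <- apply_blooming(ph50$volume, noiseless_scanner())
  mb <- measure_diameter_stenosis(bl, reference_slices = sl$reference,
                                  lesion_slices = sl$lesion)
  expect_gt(mb, 50)
  # no lumen -> measurement error
  flat <- image_volume(array(-50, dim(ph50$volume)), ph50$volume$spacing)
  expect_error(measure_diameter_stenosis(flat, reference_slices = sl$reference,
                                         lesion_slices = sl$lesion),
               "lumen")
})

test_that("area stenosis matches the analytic eccentric-occlusion oracle", {
  for (sten in c(40, 50, 70)) {
    ph <- make_vessel_phantom(small_spec(sten))
    sl <- phantom_slice_ranges(ph$truth)
    a <- measure_area_stenosis(ph$volume, reference_slices = sl$reference,
                               lesion_slices = sl$lesion)
    # the tangent plaque disc lies entirely inside the lumen, so the
    # occluded fraction is (p/2)^2 / R^2
    p <- plaque_diameter_for_stenosis(sten, 4.0)
    oracle <- 100 * (p / 2)^2 / 2^2
    expect_lt(abs(a - oracle), 3)
  }
})

test_that("diameter and area stenosis are consistent for concentric narrowing", {
  for (d_sten in c(30, 50)) {
    tube <- concentric_tube(d_sten)
    ref <- c(1:6, 19:24); les <- 10:15
    dm <- measure_diameter_stenosis(tube, reference_slices = ref,
                                    lesion_slices = les)
    am <- measure_area_stenosis(tube, reference_slices = ref,
                                lesion_slices = les)
    expect_lt(abs(dm - d_sten), 3)
    expect_lt(abs(am - 100 * (1 - (1 - d_sten / 100)^2)), 3)
  }
})

test_that("stenosis is invariant to a small global HU offset", {
  ph <- make_vessel_phantom(small_spec(50))
  sl <- phantom_slice_ranges(ph$truth)
  m <- measure_diameter_stenosis(ph$volume, reference_slices = sl$reference,
                                 lesion_slices = sl$lesion)
  shifted <- image_volume(ph$volume$voxels + 10, ph$volume$spacing)
  ms <- measure_diameter_stenosis(shifted, reference_slices = sl$reference,
                                  lesion_slices = sl$lesion)
  expect_lt(abs(ms - m), 0.5)
})

test_that("calcium_volume counts voxels times voxel volume and is monotone", {
  sp <- c(0.234375, 0.234375, 0.625)
  v <- array(0, c(10, 10, 4)); v[5, 5, 2] <- 1500
  vol <- image_volume(v, sp)
  expect_equal(calcium_volume(vol, 600), prod(sp), tolerance = 1e-9)
  expect_equal(calcium_volume(vol, 600), 0.0343323, tolerance = 1e-4)
  expect_equal(calcium_volume(vol, 1600), 0)
  expect_error(calcium_volume(vol, 0), "positive")
  # monotone non-increasing in the threshold on a real phantom
  ph <- make_vessel_phantom(small_spec(70, grid_shape = c(64L, 64L, 16L)))
  ths <- c(130, 400, 600, 800, 1000)
  vols <- vapply(ths, function(t) calcium_volume(ph$volume, t), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("snr implements CT_vessel / SD_periphery with undefined handling", {
  sp <- c(0.5, 0.5, 0.5)
  v <- array(0, c(60, 60, 12))
  vroi <- array(FALSE, dim(v)); vroi[26:35, 26:35, ] <- TRUE
  proi <- array(FALSE, dim(v)); proi[1:50, 1:50, 1:10] <- TRUE
  proi[vroi] <- FALSE
  v[vroi] <- 350
  # constant periphery -> undefined
  s0 <- snr(image_volume(v, sp), vroi, proi)
  expect_true(s0$undefined)
  expect_true(is.na(s0$snr))
  # seeded noise of SD 8 is recovered within 15% on a large ROI
  set.seed(99)
  v[proi] <- rnorm(sum(proi), sd = 8)
  s <- snr(image_volume(v, sp), vroi, proi)
  expect_equal(s$ct_vessel, 350)
  expect_lt(abs(s$sd_periphery - 8) / 8, 0.15)
  expect_equal(s$snr, s$ct_vessel / s$sd_periphery)
  expect_equal(s$noise, s$sd_periphery)
  expect_error(snr(image_volume(v, sp), vroi, vroi), "disjoint")
})
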