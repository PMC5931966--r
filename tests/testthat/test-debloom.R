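# oracle_landweber_1d lives in helper-oracle.R (shared with the acceptance
# suite).

test_that("solver core matches the brute-force Landweber oracle to 1e-10", {
  set.seed(3)
  k <- c(0.3, 0.5, 0.2) # deliberately asymmetric 3-tap kernel
  truth <- c(rep(0, 10), rep(100, 6), rep(0, 12), 40, rep(0, 7))
  y <- debloomr:::conv_sep(truth, list(k))
  for (iters in c(1L, 7L, 23L)) {
    fit <- landweber_deconvolve(y, k, alpha = 1, lambda = 0,
                                max_iter = iters, tol = 1e-15)
    expect_equal(fit$iterations, iters)
    expect_lt(max(abs(fit$x - oracle_landweber_1d(y, k, 1, iters))), 1e-10)
  }
  expect_error(landweber_deconvolve(y, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("calcium_mask thresholds and dilates as configured", {
  sp <- c(0.234375, 0.234375, 0.625)
  soft <- image_volume(array(100, c(20, 20, 8)), sp)
  expect_false(any(calcium_mask(soft)))
  # single hot voxel, 1.6 mm dilation at 0.234 mm spacing -> at least the
  # 13 x 13 in-plane neighbourhood
  v <- array(0, c(31, 31, 9)); v[16, 16, 5] <- 2000
  m <- calcium_mask(image_volume(v, sp),
                    debloom_config(mask_dilation = 1.6))
  expect_true(all(m[16 + (-6:6), 16 + (-6:6), 5]))
  # phantom plaque voxels are inside the mask
  ph <- make_vessel_phantom(small_spec(60, grid_shape = c(64L, 64L, 16L)))
  m2 <- calcium_mask(ph$volume, debloom_config(mask_dilation = 1.6))
  expect_true(all(m2[ph$volume$voxels >= 1097]))
})

test_that("residual_norm obeys its contract", {
  sp <- c(0.5, 0.5, 0.5)
  obs <- image_volume(array(rnorm(6^3), c(6, 6, 6)), sp)
  idpsf <- build_psf(scanner_config("STND"), sp)
  idpsf$taps <- list(1, 1, 1) # identity kernel
  expect_equal(residual_norm(obs, obs, idpsf), 0)
  zero <- image_volume(array(0, c(6, 6, 6)), sp)
  expect_equal(residual_norm(obs, zero, idpsf), sqrt(sum(obs$voxels^2)))
  expect_error(residual_norm(obs, image_volume(array(0, c(5, 6, 6)), sp), idpsf),
               "shapes")
  # forward-model round trip: estimate = truth under the matched PSF
  ph <- make_vessel_phantom(small_spec(50, grid_shape = c(64L, 64L, 16L)))
  cfg <- noiseless_scanner()
  psf <- build_psf(cfg, ph$volume$spacing)
  bl <- apply_blooming(ph$volume, cfg, psf)
  expect_lt(residual_norm(bl, ph$volume, psf) / sqrt(sum(bl$voxels^2)), 1e-6)
})

test_that("debloom is the identity under an identity PSF and outside the mask", {
  ph <- make_vessel_phantom(small_spec(50, grid_shape = c(64L, 64L, 16L)))
  cfg <- noiseless_scanner()
  psf <- build_psf(cfg, ph$volume$spacing)
  bl <- apply_blooming(ph$volume, cfg, psf)
  idpsf <- psf; idpsf$taps <- list(1, 1, 1)
  out <- debloom(bl, idpsf)
  expect_identical(out$volume$voxels, bl$voxels)
  expect_equal(out$report$iterations, 0L)
  # masked application: outside the dilated mask, bit-for-bit identical
  res <- debloom(bl, psf)
  mask <- calcium_mask(bl, debloom_config(mask_dilation = 2 * psf$fwhm[1]))
  expect_identical(res$volume$voxels[!mask], bl$voxels[!mask])
  expect_false(identical(res$volume$voxels[mask], bl$voxels[mask]))
  # empty mask -> explicit no-op
  soft <- image_volume(array(100, c(16, 16, 8)), bl$spacing)
  noop <- debloom(soft, psf)
  expect_true(noop$report$noop)
  expect_identical(noop$volume$voxels, soft$voxels)
  expect_equal(noop$report$stop_reason, "no-op")
  # a non-normalized PSF is rejected
  bad <- psf; bad$taps[[1]] <- c(0.5, 0.5, 0.5)
  expect_error(debloom(bl, bad), "sum to 1")
})

test_that("residual trajectory is non-increasing for alpha <= 1, lambda = 0", {
  ph <- make_vessel_phantom(small_spec(60))
  cfg <- scanner_config("STND", seed = 2) # noise + rim on
  psf <- build_psf(cfg, ph$volume$spacing)
  bl <- apply_blooming(ph$volume, cfg, psf)
  for (alpha in c(0.5, 1.0)) {
    res <- debloom(bl, psf, debloom_config(step_size = alpha, lambda = 0,
                                           max_iter = 30, tol = 1e-12))
    expect_true(all(diff(res$report$residuals) <= 1e-9))
  }
})

test_that("matched-PSF deconvolution substantially restores the truth in the mask", {
  # Noiseless, rim-free, lambda 0: Landweber halves the in-mask RMSE within
  # 50 iterations (sharp-edge high frequencies keep it from full recovery;
  # measured ~75 HU vs ~123 HU for the observed image).
  ph <- make_vessel_phantom(small_spec(50))
  cfg <- noiseless_scanner()
  psf <- build_psf(cfg, ph$volume$spacing)
  bl <- apply_blooming(ph$volume, cfg, psf)
  mask <- calcium_mask(bl, debloom_config(mask_dilation = 2 * psf$fwhm[1]))
  res <- debloom(bl, psf, debloom_config(lambda = 0))
  rmse <- function(v) sqrt(mean((v - ph$volume$voxels)[mask]^2))
  expect_lt(rmse(res$volume$voxels), 85)
  expect_lt(rmse(res$volume$voxels), 0.7 * rmse(bl$voxels))
})

test_that("de-blooming shrinks calcium volume where the bloom halo dominates", {
  # The 600 HU volume decreases when the halo the PSF creates outweighs the
  # partial-volume dilution of the plaque's own boundary voxels: measured,
  # that is plaques >= 1.2 mm under STND and >= 2.0 mm under the sharper
  # HD_STND kernel (whose near-delta PSF dilutes more than it halos).
  cases <- rbind(expand.grid(kern = "STND", sten = c(30, 60, 90)),
                 expand.grid(kern = "HD_STND", sten = c(50, 70, 90)))
  for (ci in seq_len(nrow(cases))) {
    kern <- as.character(cases$kern[ci]); sten <- cases$sten[ci]
    ph <- make_vessel_phantom(small_spec(sten))
    cfg <- scanner_config(kern, seed = 40 + sten)
    psf <- build_psf(cfg, ph$volume$spacing)
    bl <- apply_blooming(ph$volume, cfg, psf)
    res <- debloom(bl, psf)
    expect_lt(calcium_volume(res$volume), calcium_volume(bl))
  }
  # noiseless 50% case: measured stenosis strictly closer to truth
  ph <- make_vessel_phantom(small_spec(50))
  cfg <- noiseless_scanner()
  psf <- build_psf(cfg, ph$volume$spacing)
  bl <- apply_blooming(ph$volume, cfg, psf)
  res <- debloom(bl, psf)
  sl <- phantom_slice_ranges(ph$truth)
  os <- measure_diameter_stenosis(bl, reference_slices = sl$reference,
                                  lesion_slices = sl$lesion)
  ds <- measure_diameter_stenosis(res$volume, reference_slices = sl$reference,
                                  lesion_slices = sl$lesion)
  expect_gt(os, 50)
  expect_lt(abs(ds - 50), abs(os - 50))
})
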