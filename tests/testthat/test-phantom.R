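test_that("plaque_diameter_for_stenosis maps the printed series and inverts exactly", {
  expect_equal(plaque_diameter_for_stenosis(90, 4.0), 3.6)
  expect_equal(plaque_diameter_for_stenosis(0, 4.0), 0.0)
  expect_equal(plaque_diameter_for_stenosis(50, 3.5), 1.75)
  # linearity / exact invertibility
  for (s in seq(0, 100, by = 12.5)) for (d in c(3.5, 4.0)) {
    p <- plaque_diameter_for_stenosis(s, d)
    expect_equal(p / d * 100, s)
  }
  expect_error(plaque_diameter_for_stenosis(-1, 4), "stenosis")
  expect_error(plaque_diameter_for_stenosis(101, 4), "stenosis")
  expect_error(plaque_diameter_for_stenosis(50, 0), "lumen")
})

test_that("phantom rasterization matches the stated geometry and materials", {
  ph <- make_vessel_phantom(small_spec(50))
  expect_s3_class(ph$volume, "image_volume")
  expect_equal(ph$truth$true_stenosis_pct, 50)
  # analytic full-cylinder volume vs partial-volume rasterization, <= 2%
  expect_equal(ph$truth$true_calcium_volume, pi * 1^2 * 4)
  expect_lt(abs(ph$truth$calcium_volume_raster - ph$truth$true_calcium_volume) /
              ph$truth$true_calcium_volume, 0.02)
  # plaque-free lumen ROI reads the contrast value to within 1 HU
  sl <- phantom_slice_ranges(ph$truth)
  ctr <- (dim(ph$volume)[1:2] + 1) / 2
  core <- ph$volume$voxels[ctr[1] + (-2:2), ctr[2] + (-2:2), sl$reference]
  expect_lt(abs(mean(core) - 350), 1)
  # stenosis-free spec inserts no calcium
  ph0 <- make_vessel_phantom(small_spec(0))
  expect_true(all(ph0$volume$voxels < 600))
  expect_equal(ph0$truth$true_calcium_volume, 0)
})

test_that("rasterized plaque volume converges with supersampling", {
  spec <- small_spec(70, grid_shape = c(64L, 64L, 24L))
  err <- vapply(c(1L, 4L, 8L), function(ss) {
    ph <- make_vessel_phantom(spec, supersample = ss)
    abs(ph$truth$calcium_volume_raster - ph$truth$true_calcium_volume) /
      ph$truth$true_calcium_volume
  }, numeric(1))
  expect_lt(err[2], 0.02)
  expect_lt(err[3], err[1])
})

test_that("spec validation enforces the domain invariants", {
  expect_error(phantom_spec(stenosis_pct = 120), "stenosis")
  expect_error(phantom_spec(spacing = c(0.2, 0.2, 0)), "spacing")
  expect_error(phantom_spec(plaque_hu = 4000), "HU")
  expect_error(phantom_spec(plaque_hu = 1500, contrast_hu = 1600,
                            contrast_hu_range = c(1500, 1700)),
               "plaque_hu > contrast_hu")
  # vessel + wall + margin must fit the grid
  tiny <- small_spec(50, grid_shape = c(16L, 16L, 24L))
  expect_error(make_vessel_phantom(tiny), "grid too small")
})

test_that("make_stenosis_series reproduces the printed plaque-size ladder", {
  series <- make_stenosis_series(small_spec(grid_shape = c(64L, 64L, 16L)),
                                 seq(10, 90, by = 10), seed = 11)
  expect_length(series, 9L)
  dia <- vapply(series, function(m)
    plaque_diameter_for_stenosis(m$truth$spec$stenosis_pct,
                                 m$truth$spec$lumen_diameter), numeric(1))
  expect_equal(dia, seq(0.4, 3.6, by = 0.4))
  vols <- vapply(series, function(m) m$truth$true_calcium_volume, numeric(1))
  expect_true(all(diff(vols) > 0))
  # one contrast draw per series, one plaque draw per member, seeded
  con <- vapply(series, function(m) m$truth$spec$contrast_hu, numeric(1))
  expect_equal(length(unique(con)), 1L)
  expect_true(con[1] >= 335 && con[1] <= 365)
  phu <- vapply(series, function(m) m$truth$spec$plaque_hu, numeric(1))
  expect_true(all(phu >= 1097 & phu <= 2910))
  series2 <- make_stenosis_series(small_spec(grid_shape = c(64L, 64L, 16L)),
                                  seq(10, 90, by = 10), seed = 11)
  expect_identical(series[[3]]$volume$voxels, series2[[3]]$volume$voxels)
  # singleton and bounds
  expect_length(make_stenosis_series(small_spec(grid_shape = c(64L, 64L, 16L)),
                                     50, seed = 1), 1L)
  expect_error(make_stenosis_series(small_spec(), numeric(0)), "non-empty")
  expect_error(make_stenosis_series(small_spec(), c(10, 96)), "95")
})
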