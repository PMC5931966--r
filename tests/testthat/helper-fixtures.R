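# Shared fixtures: small-grid phantoms and index helpers. Everything is
# generated in code; no binary fixtures ship with the package.

# Compact grid that still leaves > 2 mm of plaque-free reference lumen at
# both ends (24 slices x 0.625 mm around a 4 mm central plaque).
small_spec <- function(stenosis_pct = 50, lumen_diameter = 4.0,
                       plaque_hu = 2000, contrast_hu = 350,
                       grid_shape = c(96L, 96L, 24L), ...) {
  phantom_spec(stenosis_pct = stenosis_pct, lumen_diameter = lumen_diameter,
               plaque_hu = plaque_hu, contrast_hu = contrast_hu,
               grid_shape = grid_shape, ...)
}

# mm -> per-axis voxel radii for mask dilation.
mm_radii <- function(mm, spacing) as.integer(round(mm / spacing))

noiseless_scanner <- function(kernel = "STND", rim = 0) {
  scanner_config(kernel, noise_sd = 0, rim_strength = rim)
}

# A concentric stenosis tube built directly (not via the phantom module):
# lumen radius narrows in the central slices. Used as an independent
# geometry for the diameter/area consistency checks.
concentric_tube <- function(d_sten_pct, lumen_diameter = 4.0,
                            grid = c(96L, 96L, 24L),
                            spacing = c(0.234375, 0.234375, 0.625),
                            contrast = 350, wall = 120, background = -50,
                            lesion = 10:15) {
  ctr <- (grid[1:2] + 1) / 2
  ss <- 4L
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  xi <- rep(seq_len(grid[1]) - ctr[1], each = ss) + rep(sub, grid[1])
  yi <- rep(seq_len(grid[2]) - ctr[2], each = ss) + rep(sub, grid[2])
  r <- sqrt(outer((xi * spacing[1])^2, (yi * spacing[2])^2, `+`))
  R <- lumen_diameter / 2
  Rn <- R * (1 - d_sten_pct / 100)
  pool <- function(m) {
    m <- matrix(colMeans(matrix(m, nrow = ss)), nrow = grid[1])
    t(matrix(colMeans(matrix(t(m), nrow = ss)), nrow = grid[2]))
  }
  base <- matrix(background, length(xi), length(yi))
  base[r <= R + 1] <- wall
  wide <- base; wide[r <= R] <- contrast
  narrow <- base; narrow[r <= Rn] <- contrast
  wide <- pool(wide); narrow <- pool(narrow)
  vox <- array(0, grid)
  for (k in seq_len(grid[3]))
    vox[, , k] <- if (k %in% lesion) narrow else wide
  image_volume(vox, spacing)
}
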