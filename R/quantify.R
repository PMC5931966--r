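# Quantification: lumen segmentation, stenosis calipers, calcium volume, SNR.
#
# Lumen segmentation uses the full-width-at-half-maximum convention: a voxel
# is lumen when its HU is at or above the half-way point between an in-image
# lumen reference and background reference, and below the calcium threshold.
# Because the thresholds come from in-image references, the measurements are
# invariant to small global HU offsets and independent of the display window
# (the clinical 1500/300 window only affects rendering).

# Bilinear interpolation of a matrix at fractional (1-based) indices.
bilinear <- function(mat, xi, yi) {
  nx <- nrow(mat); ny <- ncol(mat)
  xi <- pmin(pmax(xi, 1), nx)
  yi <- pmin(pmax(yi, 1), ny)
  x0 <- pmin(floor(xi), nx - 1L); y0 <- pmin(floor(yi), ny - 1L)
  fx <- xi - x0; fy <- yi - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  mat[i00] * (1 - fx) * (1 - fy) + mat[i10] * fx * (1 - fy) +
    mat[i01] * (1 - fx) * fy + mat[i11] * fx * fy
}

# In-plane voxel-centre grid centre (continuous 1-based index) of a volume.
slice_center_index <- function(vol) (dim(vol$voxels)[1:2] + 1) / 2

# Mean HU in a disc of radius `r_mm` around `center` (index units) averaged
# over `slices`.
disc_mean_hu <- function(vol, slices, center, r_mm) {
  sp <- vol$spacing[1:2]
  d <- dim(vol$voxels)
  xi <- seq_len(d[1]); yi <- seq_len(d[2])
  in_disc <- outer(((xi - center[1]) * sp[1])^2,
                   ((yi - center[2]) * sp[2])^2, `+`) <= r_mm^2
  mean(vapply(slices, function(k) mean(vol$voxels[, , k][in_disc]),
              numeric(1)))
}

# Reference thresholds from plaque-free slices: lumen HU at the vessel
# centre, background HU in the grid corners, and the FWHM lumen threshold.
reference_thresholds <- function(vol, reference_slices, center = NULL) {
  center <- center %||% slice_center_index(vol)
  lumen_hu <- disc_mean_hu(vol, reference_slices, center, r_mm = 0.5)
  d <- dim(vol$voxels)
  cs <- max(2L, min(8L, d[1] %/% 8L))
  corner <- vol$voxels[c(seq_len(cs), d[1] - seq_len(cs) + 1L),
                       c(seq_len(cs), d[2] - seq_len(cs) + 1L),
                       reference_slices]
  background_hu <- mean(corner)
  list(lumen_hu = lumen_hu, background_hu = background_hu,
       threshold = (lumen_hu + background_hu) / 2)
}

# Direction (unit vector, index space) from the vessel centre towards the
# plaque: the HU-weighted centroid of calcium voxels in the lesion slices,
# falling back to the hottest voxel when nothing crosses the threshold.
plaque_direction <- function(vol, lesion_slices, center, calcium_threshold) {
  sub <- vol$voxels[, , lesion_slices, drop = FALSE]
  hot <- sub >= calcium_threshold
  if (any(hot)) {
    w <- which(hot, arr.ind = TRUE)
    wt <- sub[hot]
    cx <- sum(w[, 1] * wt) / sum(wt)
    cy <- sum(w[, 2] * wt) / sum(wt)
  } else {
    w <- which(sub == max(sub), arr.ind = TRUE)[1, , drop = FALSE]
    cx <- w[1, 1]; cy <- w[1, 2]
  }
  v <- c(cx - center[1], cy - center[2])
  if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0)
  v / sqrt(sum(v^2))
}

# Free-lumen extent (mm) along the line through `center` with direction
# `dir` on one slice: length of the longest contiguous run of lumen-classed
# samples.
free_chord_mm <- function(slice_mat, center, dir, spacing, t_lumen,
                          calcium_threshold, half_span_mm, step_mm) {
  t_steps <- seq(-half_span_mm, half_span_mm, by = step_mm)
  xi <- center[1] + t_steps * dir[1] / spacing[1]
  yi <- center[2] + t_steps * dir[2] / spacing[2]
  hu <- bilinear(slice_mat, xi, yi)
  lum <- hu >= t_lumen & hu < calcium_threshold
  if (!any(lum)) return(0)
  r <- rle(lum)
  max(r$lengths[r$values]) * step_mm
}

measure_context <- function(image, axis, reference_slices, lesion_slices,
                            center, calcium_threshold) {
  stopifnot(is_image_volume(image))
  if (axis != 3L) stop("only axis = 3 (z) measurements are supported")
  if (length(reference_slices) < 1L || length(lesion_slices) < 1L)
    stop("need at least one reference and one lesion slice")
  center <- center %||% slice_center_index(image)
  refs <- reference_thresholds(image, reference_slices, center)
  if (refs$lumen_hu <= refs$background_hu + 25)
    stop("no contrast-filled lumen detected in the reference slices")
  dir <- plaque_direction(image, lesion_slices, center, calcium_threshold)
  list(center = center, refs = refs, dir = dir)
}

#' Measure percent diameter stenosis
#'
#' Emulates a caliper measurement across the lesion: per slice the lumen is
#' segmented by the half-maximum rule (threshold midway between in-image
#' lumen and background references, calcium excluded above
#' `calcium_threshold`), and the free-lumen diameter is the longest
#' contiguous lumen run along the diameter through the plaque centroid.
#' Diameter stenosis is `(1 - min lesion diameter / mean reference
#' diameter) * 100`, clipped to `[0, 100]`. With `method = "area"` the
#' per-slice diameter is instead the effective diameter
#' `2 * sqrt(lumen area / pi)`, which understates eccentric stenoses and is
#' provided for concentric lesions.
#'
#' @param image an [image_volume()].
#' @param axis vessel axis (only 3 supported).
#' @param reference_slices indices of plaque-free slices.
#' @param lesion_slices indices spanning the plaque.
#' @param center in-plane vessel-centre index (continuous, 1-based);
#'   defaults to the grid centre.
#' @param method `"caliper"` (default) or `"area"`.
#' @param calcium_threshold HU above which voxels count as calcium and are
#'   excluded from the lumen.
#' @param window display window `(width, level)`; retained for API
#'   compatibility with rendered review, not used by the segmentation
#'   (thresholds are window-independent).
#' @return Percent stenosis in `[0, 100]`.
#' @export
measure_diameter_stenosis <- function(image, axis = 3L, reference_slices,
                                      lesion_slices, center = NULL,
                                      method = c("caliper", "area"),
                                      calcium_threshold = 600,
                                      window = c(1500, 300)) {
  method <- match.arg(method)
  ctx <- measure_context(image, axis, reference_slices, lesion_slices,
                         center, calcium_threshold)
  if (method == "area") {
    areas <- lumen_areas(image, c(reference_slices, lesion_slices),
                         ctx$refs$threshold, calcium_threshold)
    dia <- 2 * sqrt(areas / pi)
    ref_d <- mean(dia[seq_along(reference_slices)])
    les_d <- min(dia[-seq_along(reference_slices)])
  } else {
    half_span <- image$spacing[1] * dim(image$voxels)[1] / 2
    step <- min(image$spacing[1:2]) / 4
    chord <- function(k) free_chord_mm(image$voxels[, , k], ctx$center,
                                       ctx$dir, image$spacing[1:2],
                                       ctx$refs$threshold, calcium_threshold,
                                       half_span, step)
    ref_d <- mean(vapply(reference_slices, chord, numeric(1)))
    les_d <- min(vapply(lesion_slices, chord, numeric(1)))
  }
  if (ref_d <= 0) stop("no lumen detected in the reference slices")
  min(100, max(0, (1 - les_d / ref_d) * 100))
}

lumen_areas <- function(image, slices, t_lumen, calcium_threshold) {
  pix <- prod(image$spacing[1:2])
  vapply(slices, function(k) {
    s <- image$voxels[, , k]
    sum(s >= t_lumen & s < calcium_threshold) * pix
  }, numeric(1))
}

#' Measure percent area stenosis
#'
#' As [measure_diameter_stenosis()] but on the segmented lumen
#' cross-sectional area: `(1 - min lesion area / mean reference area) * 100`,
#' clipped to `[0, 100]`.
#'
#' @inheritParams measure_diameter_stenosis
#' @return Percent area stenosis in `[0, 100]`.
#' @export
measure_area_stenosis <- function(image, axis = 3L, reference_slices,
                                  lesion_slices, center = NULL,
                                  calcium_threshold = 600,
                                  window = c(1500, 300)) {
  ctx <- measure_context(image, axis, reference_slices, lesion_slices,
                         center, calcium_threshold)
  ref_a <- mean(lumen_areas(image, reference_slices, ctx$refs$threshold,
                            calcium_threshold))
  les_a <- min(lumen_areas(image, lesion_slices, ctx$refs$threshold,
                           calcium_threshold))
  if (ref_a <= 0) stop("no lumen detected in the reference slices")
  min(100, max(0, (1 - les_a / ref_a) * 100))
}

#' Calcium volume above a threshold
#'
#' Count of voxels at or above `threshold` times the voxel volume. The
#' default 600 HU separates contrast-filled lumen (<= ~365 HU) from
#' calcification (>= ~1097 HU) with margin; the classic 130 HU scoring
#' threshold would swallow the contrast pool.
#'
#' @param image an [image_volume()].
#' @param threshold HU, must be positive.
#' @return Volume in mm^3.
#' @export
calcium_volume <- function(image, threshold = 600) {
  stopifnot(is_image_volume(image))
  if (threshold <= 0) stop("threshold must be positive")
  sum(image$voxels >= threshold) * voxel_volume(image)
}

#' Signal-to-noise ratio of the vessel
#'
#' `SNR = mean HU in the vessel ROI / SD of HU in the periphery ROI`; the
#' periphery SD doubles as the image-noise estimate.
#'
#' @param image an [image_volume()].
#' @param vessel_roi,periphery_roi logical arrays (volume dimensions)
#'   selecting a plaque-free lumen region and a background region; must be
#'   non-empty and disjoint.
#' @return An object of class `snr_measurement`: `ct_vessel`, `sd_periphery`,
#'   `snr`, `noise`, and `undefined` (TRUE when the periphery has zero
#'   variance).
#' @export
snr <- function(image, vessel_roi, periphery_roi) {
  stopifnot(is_image_volume(image))
  if (!any(vessel_roi) || !any(periphery_roi))
    stop("ROIs must be non-empty")
  if (any(vessel_roi & periphery_roi)) stop("ROIs must be disjoint")
  ct_vessel <- mean(image$voxels[vessel_roi])
  sd_periphery <- stats::sd(image$voxels[periphery_roi])
  undefined <- !is.finite(sd_periphery) || sd_periphery == 0
  structure(list(ct_vessel = ct_vessel,
                 sd_periphery = sd_periphery,
                 snr = if (undefined) NA_real_ else ct_vessel / sd_periphery,
                 noise = sd_periphery,
                 undefined = undefined),
            class = "snr_measurement")
}

#' @export
print.snr_measurement <- function(x, ...) {
  if (x$undefined) cat("<snr_measurement> undefined (zero-variance periphery)\n")
  else cat(sprintf("<snr_measurement> vessel %.1f HU, noise %.2f HU, SNR %.1f\n",
                   x$ct_vessel, x$noise, x$snr))
  invisible(x)
}
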