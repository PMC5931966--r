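#' Specification of a digital calcified-vessel phantom
#'
#' Describes one straight, contrast-filled coronary vessel with an acrylic
#' wall and (optionally) a single eccentric calcified plaque. The plaque is a
#' full cylinder of diameter `stenosis_pct/100 * lumen_diameter` running
#' parallel to the vessel axis and internally tangent to the inner wall, so
#' the free lumen along the diameter through the plaque centre is reduced by
#' exactly the plaque diameter -- the convention under which a 3.6 mm plaque
#' in a 4.0 mm lumen is a 90% diameter stenosis.
#'
#' Plaque and contrast attenuations may be fixed numbers or `NULL`, in which
#' case [make_vessel_phantom()] draws them uniformly from the hydroxyapatite
#' range 1097--2910 HU and the diluted-contrast range 335--365 HU (values at
#' 100 kVp).
#'
#' @param lumen_diameter inner vessel diameter, mm (3.5 and 4.0 are the
#'   studied sizes).
#' @param wall_thickness acrylic wall thickness, mm.
#' @param stenosis_pct target diameter stenosis, percent in `[0, 100]`.
#' @param plaque_length plaque extent along the vessel axis, mm.
#' @param plaque_hu plaque attenuation in HU, or `NULL` to draw from
#'   `plaque_hu_range`.
#' @param contrast_hu lumen attenuation in HU, or `NULL` to draw from
#'   `contrast_hu_range`.
#' @param wall_hu,background_hu wall and background attenuations, HU.
#' @param plaque_hu_range,contrast_hu_range uniform draw ranges, HU.
#' @param vessel_axis array dimension the vessel runs along (only 3 is
#'   currently supported).
#' @param grid_shape voxel grid dimensions.
#' @param spacing mm per voxel; the in-plane default is DFOV 120 mm / 512.
#' @return An object of class `phantom_spec`.
#' @seealso [make_vessel_phantom()], [make_stenosis_series()]
#' @export
phantom_spec <- function(lumen_diameter = 4.0,
                         wall_thickness = 1.0,
                         stenosis_pct = 50,
                         plaque_length = 4.0,
                         plaque_hu = NULL,
                         contrast_hu = NULL,
                         wall_hu = 120,
                         background_hu = -50,
                         plaque_hu_range = c(1097, 2910),
                         contrast_hu_range = c(335, 365),
                         vessel_axis = 3L,
                         grid_shape = c(256L, 256L, 64L),
                         spacing = c(0.234375, 0.234375, 0.625)) {
  spec <- structure(list(
    lumen_diameter = lumen_diameter, wall_thickness = wall_thickness,
    stenosis_pct = stenosis_pct, plaque_length = plaque_length,
    plaque_hu = plaque_hu, contrast_hu = contrast_hu,
    wall_hu = wall_hu, background_hu = background_hu,
    plaque_hu_range = plaque_hu_range, contrast_hu_range = contrast_hu_range,
    vessel_axis = as.integer(vessel_axis),
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (lumen_diameter <= 0) stop("lumen_diameter must be positive")
    if (wall_thickness < 0) stop("wall_thickness must be non-negative")
    if (stenosis_pct < 0 || stenosis_pct > 100)
      stop("stenosis_pct must be in [0, 100]")
    if (plaque_length <= 0) stop("plaque_length must be positive")
    if (vessel_axis != 3L) stop("only vessel_axis = 3 (z) is supported")
    if (length(grid_shape) != 3L || any(grid_shape < 8L))
      stop("grid_shape must be 3 dimensions of at least 8 voxels")
    if (any(spacing <= 0)) stop("spacing must be strictly positive")
    hu_fixed <- c(plaque_hu, contrast_hu, wall_hu, background_hu,
                  plaque_hu_range, contrast_hu_range)
    if (any(hu_fixed < -1024 | hu_fixed > 3071))
      stop("all HU values must lie within [-1024, 3071]")
    if (min(plaque_hu_range) <= max(contrast_hu_range) ||
        min(contrast_hu_range) <= background_hu)
      stop("need plaque_hu > contrast_hu > background_hu")
    if (!is.null(plaque_hu) && !is.null(contrast_hu) &&
        (plaque_hu <= contrast_hu || contrast_hu <= background_hu))
      stop("need plaque_hu > contrast_hu > background_hu")
  })
  invisible(spec)
}

#' Plaque diameter corresponding to a diameter stenosis
#'
#' The linear (and exactly invertible) mapping used to build the stenosis
#' series: a plaque of diameter `stenosis_pct/100 * lumen_diameter` tangent
#' to the inner wall leaves a free lumen of
#' `lumen_diameter - plaque_diameter` along the diameter through its centre.
#'
#' @param stenosis_pct percent diameter stenosis in `[0, 100]`.
#' @param lumen_diameter inner vessel diameter, mm.
#' @return Plaque diameter in mm.
#' @examples
#' plaque_diameter_for_stenosis(90, 4.0) # 3.6 mm
#' @export
plaque_diameter_for_stenosis <- function(stenosis_pct, lumen_diameter) {
  if (any(stenosis_pct < 0) || any(stenosis_pct > 100))
    stop("stenosis_pct must be in [0, 100]")
  if (any(lumen_diameter <= 0)) stop("lumen_diameter must be positive")
  stenosis_pct / 100 * lumen_diameter
}

# Anti-aliased 2-D cross-section maps at `ss`-fold in-plane supersampling.
# Returns mean-HU maps with and without the plaque, plus the per-pixel plaque
# area fraction. x0/y0 are the vessel-axis coordinates (mm).
cross_section_maps <- function(spec, contrast_hu, plaque_hu, ss) {
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  sx <- spec$spacing[1]; sy <- spec$spacing[2]
  x0 <- (nx - 1) / 2 * sx
  y0 <- (ny - 1) / 2 * sy
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  xs <- rep((seq_len(nx) - 1) * sx, each = ss) + rep(sub * sx, times = nx)
  ys <- rep((seq_len(ny) - 1) * sy, each = ss) + rep(sub * sy, times = ny)
  R <- spec$lumen_diameter / 2
  Rw <- R + spec$wall_thickness
  p <- plaque_diameter_for_stenosis(spec$stenosis_pct, spec$lumen_diameter)
  # plaque axis offset: tangent internally to the inner wall, along +x
  pcx <- x0 + (R - p / 2)
  dx2 <- (xs - x0)^2
  dy2 <- (ys - y0)^2
  r2 <- outer(dx2, dy2, `+`)
  base <- matrix(spec$background_hu, length(xs), length(ys))
  base[r2 <= Rw^2] <- spec$wall_hu
  base[r2 <= R^2] <- contrast_hu
  if (p > 0) {
    pr2 <- outer((xs - pcx)^2, dy2, `+`)
    in_plaque <- pr2 <= (p / 2)^2
  } else {
    in_plaque <- matrix(FALSE, length(xs), length(ys))
  }
  with_plaque <- base
  with_plaque[in_plaque] <- plaque_hu
  pool <- function(m) {
    # average ss x ss blocks
    m <- matrix(colMeans(matrix(m, nrow = ss)), nrow = nx)  # pool x
    t(matrix(colMeans(matrix(t(m), nrow = ss)), nrow = ny)) # pool y
  }
  list(with_plaque = pool(with_plaque),
       without_plaque = pool(base),
       plaque_frac = pool(in_plaque + 0),
       center = c(x0, y0))
}

#' Rasterize a vessel phantom and its ground truth
#'
#' Builds the HU volume for one [phantom_spec()]: a straight vessel along z
#' with concentric lumen and wall, and an eccentric cylindrical plaque of
#' `plaque_length` mm centred axially in the grid. Material boundaries are
#' anti-aliased: each voxel takes the volume-weighted mean HU, computed by
#' in-plane supersampling (factor `supersample` per axis) and exact axial
#' interval overlap (the geometry is z-extruded).
#'
#' @param spec a [phantom_spec()].
#' @param supersample in-plane supersampling factor per axis (>= 4 keeps the
#'   rasterized plaque volume within 2% of the analytic cylinder volume).
#' @return A list with elements
#'   \describe{
#'     \item{volume}{the [image_volume()] ground-truth HU grid,}
#'     \item{truth}{a `truth_record`: the resolved spec (HU draws filled in),
#'       `true_stenosis_pct`, analytic `true_calcium_volume` (mm^3), the
#'       rasterized `calcium_volume_raster` (mm^3), the `plaque_centroid`
#'       (mm) and the axial voxel range `plaque_slices` covered by the
#'       plaque.}
#'   }
#' @details HU values left `NULL` in the spec are drawn uniformly from the
#'   spec's ranges using the current RNG stream; seed callers that need
#'   reproducibility (see [make_stenosis_series()]).
#' @export
make_vessel_phantom <- function(spec, supersample = 4L) {
  validate_phantom_spec(spec)
  ss <- as.integer(supersample)
  if (ss < 1L) stop("supersample must be >= 1")
  Rw <- spec$lumen_diameter / 2 + spec$wall_thickness
  fov <- spec$grid_shape[1:2] * spec$spacing[1:2]
  if (2 * Rw + 2 > min(fov))
    stop("grid too small: vessel plus wall does not fit with a 1 mm margin")

  contrast_hu <- spec$contrast_hu %||% runif(1, spec$contrast_hu_range[1],
                                             spec$contrast_hu_range[2])
  plaque_hu <- spec$plaque_hu %||% runif(1, spec$plaque_hu_range[1],
                                         spec$plaque_hu_range[2])
  spec$contrast_hu <- contrast_hu
  spec$plaque_hu <- plaque_hu

  maps <- cross_section_maps(spec, contrast_hu, plaque_hu, ss)
  nz <- spec$grid_shape[3]; sz <- spec$spacing[3]
  zc <- (nz - 1) / 2 * sz
  L <- spec$plaque_length
  z_lo <- zc - L / 2; z_hi <- zc + L / 2
  vox <- array(0, spec$grid_shape)
  p <- plaque_diameter_for_stenosis(spec$stenosis_pct, spec$lumen_diameter)
  zfrac <- numeric(nz)
  for (k in seq_len(nz)) {
    lo <- (k - 1) * sz - sz / 2
    hi <- lo + sz
    f <- if (p > 0) max(0, min(hi, z_hi) - max(lo, z_lo)) / sz else 0
    zfrac[k] <- f
    vox[, , k] <- f * maps$with_plaque + (1 - f) * maps$without_plaque
  }
  vol <- image_volume(vox, spec$spacing)

  pix_area <- prod(spec$spacing[1:2])
  raster_vol <- sum(maps$plaque_frac) * pix_area * sum(zfrac) * sz
  analytic_vol <- if (p > 0) pi * (p / 2)^2 * L else 0
  R <- spec$lumen_diameter / 2
  centroid <- c(maps$center[1] + (R - p / 2), maps$center[2], zc)
  plaque_slices <- if (p > 0) range(which(zfrac > 0)) else c(NA_integer_, NA_integer_)

  truth <- structure(list(
    spec = spec,
    true_stenosis_pct = spec$stenosis_pct,
    true_calcium_volume = analytic_vol,
    calcium_volume_raster = raster_vol,
    plaque_centroid = centroid,
    plaque_slices = plaque_slices),
    class = "truth_record")
  list(volume = vol, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a series of phantoms over a range of stenoses
#'
#' One phantom per requested stenosis, identical apart from the plaque
#' diameter. The contrast attenuation is drawn once for the whole series
#' (one physical vessel) and the plaque attenuation once per member (each
#' plaque is a distinct insert), both uniformly within the spec's ranges,
#' reproducibly from `seed`.
#'
#' @param base_spec a [phantom_spec()]; its `stenosis_pct` is overridden.
#' @param stenoses percent stenoses, each in `[0, 95]`.
#' @param seed integer seed for the HU draws, or `NULL` to use the ambient
#'   RNG stream.
#' @param supersample passed to [make_vessel_phantom()].
#' @return A list with one `list(volume, truth)` element per stenosis.
#' @examples
#' series <- make_stenosis_series(
#'   phantom_spec(grid_shape = c(64, 64, 16)), stenoses = c(30, 60), seed = 1)
#' sapply(series, function(m) m$truth$true_calcium_volume)
#' @export
make_stenosis_series <- function(base_spec, stenoses = seq(10, 90, by = 10),
                                 seed = NULL, supersample = 4L) {
  if (length(stenoses) == 0L) stop("`stenoses` must be non-empty")
  if (any(stenoses < 0) || any(stenoses > 95))
    stop("each stenosis must be in [0, 95]")
  with_seed(seed, {
    contrast <- base_spec$contrast_hu %||%
      runif(1, base_spec$contrast_hu_range[1], base_spec$contrast_hu_range[2])
    lapply(seq_along(stenoses), function(i) {
      spec <- base_spec
      spec$stenosis_pct <- stenoses[i]
      spec$contrast_hu <- contrast
      make_vessel_phantom(spec, supersample = supersample)
    })
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf(
    "<truth_record> stenosis %.0f%%, plaque %.2f mm (%.0f HU), calcium %.2f mm^3\n",
    x$true_stenosis_pct,
    plaque_diameter_for_stenosis(x$spec$stenosis_pct, x$spec$lumen_diameter),
    x$spec$plaque_hu, x$true_calcium_volume))
  invisible(x)
}
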