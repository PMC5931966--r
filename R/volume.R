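#' Image volume in Hounsfield Units
#'
#' The universal container passed between the phantom generator, the scanner
#' forward model, the de-blooming correction and the quantification routines:
#' a 3-D array of HU values plus the physical voxel spacing and the position
#' of the first voxel centre.
#'
#' @param voxels numeric 3-D array of HU values.
#' @param spacing numeric length-3, mm per voxel along each array dimension
#'   (all strictly positive).
#' @param origin numeric length-3, mm position of voxel `[1,1,1]`.
#' @return An object of class `image_volume` (a list with elements `voxels`,
#'   `spacing`, `origin`).
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), spacing = c(0.5, 0.5, 1))
#' dim(v)
#' voxel_volume(v)
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (any(!is.finite(voxels)))
    stop("`voxels` must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' @rdname image_volume
#' @param x an `image_volume`.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' @rdname image_volume
#' @export
voxel_volume <- function(x) {
  stopifnot(is_image_volume(x))
  prod(x$spacing)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 6), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Voxel-centre coordinates (mm) along one array dimension.
axis_coords <- function(vol, axis) {
  (seq_len(dim(vol$voxels)[axis]) - 1) * vol$spacing[axis] + vol$origin[axis]
}

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("volumes have different shapes")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volumes have different spacings")
  invisible(TRUE)
}
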