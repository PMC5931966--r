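# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz).
#
# Only what the pipeline needs: 3-D volumes, float32 on write, the common
# integer/float datatypes with scl_slope/inter on read, spacing from pixdim
# and origin from the sform (or qform offset). No NIfTI R package is
# assumed; the writer is cross-checked against nibabel in the test suite.

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' Voxels are stored as little-endian float32 with spacing in `pixdim` and
#' the origin in an axis-aligned sform. `.gz` paths are gzip-compressed.
#'
#' @param volume an [image_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_image_volume(volume))
  d <- dim(volume$voxels)
  sp <- volume$spacing
  og <- volume$origin
  hcon <- rawConnection(raw(0), "wb")
  w <- function(x, size, what = "integer") writeBin(x, hcon, size = size,
                                                    endian = "little")
  pad <- function(n) writeBin(raw(n), hcon)
  w(348L, 4L)                       # sizeof_hdr
  pad(36L)                          # data_type..dim_info (unused)
  w(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  writeBin(numeric(3), hcon, size = 4L, endian = "little") # intent_p1..p3
  w(0L, 2L)                         # intent_code
  w(16L, 2L)                        # datatype float32
  w(32L, 2L)                        # bitpix
  w(0L, 2L)                         # slice_start
  writeBin(c(1, sp, 0, 0, 0, 0), hcon, size = 4L, endian = "little") # pixdim
  writeBin(352, hcon, size = 4L, endian = "little")  # vox_offset
  writeBin(c(1, 0), hcon, size = 4L, endian = "little") # scl_slope, scl_inter
  w(0L, 2L)                         # slice_end
  writeBin(as.raw(c(0L, 2L)), hcon) # slice_code; xyzt_units = mm
  writeBin(numeric(4), hcon, size = 4L, endian = "little") # cal/slice_dur/toffset
  w(c(0L, 0L), 4L)                  # glmax, glmin
  desc <- charToRaw("debloomr")
  writeBin(c(desc, raw(80L - length(desc))), hcon)  # descrip
  pad(24L)                          # aux_file
  w(0L, 2L)                         # qform_code
  w(1L, 2L)                         # sform_code
  writeBin(numeric(6), hcon, size = 4L, endian = "little") # quatern, qoffset
  srow <- rbind(c(sp[1], 0, 0, og[1]),
                c(0, sp[2], 0, og[2]),
                c(0, 0, sp[3], og[3]))
  writeBin(as.numeric(t(srow)), hcon, size = 4L, endian = "little")
  pad(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), hcon)  # magic
  writeBin(raw(4L), hcon)           # extension flag
  hdr <- rawConnectionValue(hcon)
  close(hcon)
  if (length(hdr) != 352L) stop("internal error: malformed NIfTI header")
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(volume$voxels), con, size = 4L, endian = "little")
  invisible(path)
}

raw_field <- function(hdr, offset, what, n, size, endian, signed = TRUE) {
  readBin(hdr[(offset + 1L):(offset + n * size)], what, n = n, size = size,
          endian = endian, signed = signed)
}

#' Read a volume from NIfTI-1 or a DICOM series
#'
#' `path` may be a `.nii` / `.nii.gz` file or a directory containing a
#' DICOM series (see [read_dicom_series()]). NIfTI spacing comes from
#' `pixdim`; an all-zero `pixdim` is rejected with a remediation hint.
#' `scl_slope`/`scl_inter` are applied when set.
#'
#' @param path file or directory path.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: truncated header")
  endian <- "little"
  if (raw_field(hdr, 0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (raw_field(hdr, 0L, "integer", 1L, 4L, endian) != 348L)
      stop("not a NIfTI-1 file: bad sizeof_hdr")
  }
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1")
    stop("unsupported NIfTI variant (need single-file 'n+1' magic)")
  dims <- raw_field(hdr, 40L, "integer", 8L, 2L, endian)
  nd <- dims[1]
  if (nd < 3L) stop("only 3-D volumes are supported")
  if (nd > 3L && any(dims[seq(5L, nd + 1L)] > 1L))
    stop("only 3-D volumes are supported")
  d <- dims[2:4]
  datatype <- raw_field(hdr, 70L, "integer", 1L, 2L, endian)
  pixdim <- raw_field(hdr, 76L, "double", 8L, 4L, endian)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header has no usable voxel spacing (pixdim <= 0); ",
         "set pixdim[1:3] to the voxel size in mm before importing")
  vox_offset <- raw_field(hdr, 108L, "double", 1L, 4L, endian)
  scl_slope <- raw_field(hdr, 112L, "double", 1L, 4L, endian)
  scl_inter <- raw_field(hdr, 116L, "double", 1L, 4L, endian)
  sform_code <- raw_field(hdr, 254L, "integer", 1L, 2L, endian)
  qform_code <- raw_field(hdr, 252L, "integer", 1L, 2L, endian)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- raw_field(hdr, 280L, "double", 12L, 4L, endian)
    origin <- srow[c(4L, 8L, 12L)]
  } else if (qform_code > 0L) {
    origin <- raw_field(hdr, 268L, "double", 3L, 4L, endian)
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip < 0L) stop("invalid vox_offset")
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(d)
  spec <- switch(as.character(datatype),
                 "2"   = list(what = "integer", size = 1L, signed = FALSE),
                 "4"   = list(what = "integer", size = 2L, signed = TRUE),
                 "8"   = list(what = "integer", size = 4L, signed = TRUE),
                 "16"  = list(what = "double", size = 4L, signed = TRUE),
                 "64"  = list(what = "double", size = 8L, signed = TRUE),
                 "256" = list(what = "integer", size = 1L, signed = TRUE),
                 "512" = list(what = "integer", size = 2L, signed = FALSE),
                 stop("unsupported NIfTI datatype code: ", datatype))
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  endian = endian, signed = spec$signed)
  if (length(vals) != nvox) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  image_volume(array(vals, d), spacing, origin)
}
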