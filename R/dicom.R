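# Minimal DICOM series importer: explicit-VR little-endian single-frame CT
# slices, enough to recover an HU volume (rescale slope/intercept applied)
# with spacing from PixelSpacing and the slice positions. Read-only.

dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM preamble): ", path)
  off <- 132L
  u16 <- function(o) readBin(raw[(o + 1L):(o + 2L)], "integer", size = 2L,
                             endian = "little", signed = FALSE)
  u32 <- function(o) readBin(raw[(o + 1L):(o + 4L)], "integer", size = 4L,
                             endian = "little")
  tags <- list()
  while (off + 8L <= length(raw)) {
    group <- u16(off); elem <- u16(off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupted DICOM not supported: ", path)
    if (vr %in% dicom_long_vrs) {
      len <- u32(off + 8L)
      voff <- off + 12L
    } else {
      len <- u16(off + 6L)
      voff <- off + 8L
    }
    if (len < 0L || voff + len > length(raw))
      stop("truncated DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, value = raw[seq_len(len) + voff])
    off <- voff + len
    if (key == "7FE0,0010") break
  }
  tags
}

dicom_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dicom_num <- function(tags, key, default = NULL) {
  s <- dicom_str(tags, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_u16 <- function(tags, key, default = NULL) {
  el <- tags[[key]]
  if (is.null(el)) return(default)
  readBin(el$value, "integer", size = 2L, endian = "little", signed = FALSE)
}

#' Read a DICOM series directory as an HU volume
#'
#' Parses every regular file in `dir` as an explicit-VR little-endian DICOM
#' slice, sorts slices by z position (falling back to instance number),
#' applies the rescale `HU = slope * stored + intercept`, and assembles an
#' [image_volume()]. In-plane spacing comes from PixelSpacing; slice spacing
#' from the position increments (or SliceThickness for a single slice).
#'
#' @param dir directory containing one series.
#' @return An [image_volume()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, parse_dicom_file)
  zs <- vapply(slices, function(t) {
    ipp <- dicom_num(t, "0020,0032")
    if (!is.null(ipp) && length(ipp) == 3L) ipp[3]
    else dicom_num(t, "0020,0013", default = NA_real_)[1]
  }, numeric(1))
  if (any(is.na(zs))) stop("DICOM slices lack position and instance number")
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  first <- slices[[1]]
  rows <- dicom_u16(first, "0028,0010")
  cols <- dicom_u16(first, "0028,0011")
  if (is.null(rows) || is.null(cols)) stop("DICOM slice lacks Rows/Columns")
  ps <- dicom_num(first, "0028,0030")
  if (is.null(ps) || length(ps) != 2L)
    stop("DICOM slice lacks PixelSpacing; cannot establish geometry")
  dz <- if (length(zs) > 1L) {
    steps <- diff(zs)
    if (max(steps) - min(steps) > 1e-3)
      warning("non-uniform DICOM slice spacing; using the mean")
    mean(steps)
  } else {
    dicom_num(first, "0018,0050", default = NA_real_)[1]
  }
  if (is.na(dz) || dz <= 0)
    stop("cannot determine DICOM slice spacing (need >1 slice or SliceThickness)")
  bits <- dicom_u16(first, "0028,0100", default = 16L)
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- identical(dicom_u16(first, "0028,0103", default = 0L), 1L)
  vox <- array(0, c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    t <- slices[[k]]
    px <- t[["7FE0,0010"]]
    if (is.null(px)) stop("DICOM slice lacks PixelData")
    stored <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                      endian = "little", signed = signed)
    slope <- dicom_num(t, "0028,1053", default = 1)[1]
    inter <- dicom_num(t, "0028,1052", default = 0)[1]
    vox[, , k] <- matrix(stored * slope + inter, nrow = cols)
  }
  ipp <- dicom_num(first, "0020,0032")
  origin <- if (!is.null(ipp) && length(ipp) == 3L) ipp else c(0, 0, zs[1])
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  image_volume(vox, c(ps[2], ps[1], dz), origin)
}
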