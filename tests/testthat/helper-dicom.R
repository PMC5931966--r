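# Writes a minimal explicit-VR little-endian DICOM slice, for exercising
# the importer. Synthetic fixture generator: not a general DICOM writer.
write_minimal_dicom <- function(path, pixels, pixel_spacing = c(0.5, 0.5),
                                slice_thickness = 1.0, z = 0,
                                slope = 1, intercept = 0, instance = 1L,
                                signed = TRUE) {
  stopifnot(is.matrix(pixels)) # [col (x), row (y)] to mirror read_dicom_series
  cols <- nrow(pixels); rows <- ncol(pixels)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  elem <- function(group, element, vr, value) {
    writeBin(writeBin(c(group, element), raw(), size = 2, endian = "little"),
             con)
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(raw(2), con)
      writeBin(length(value), con, size = 4, endian = "little")
    } else {
      writeBin(length(value), con, size = 2, endian = "little")
    }
    writeBin(value, con)
  }
  ds <- function(x) {
    s <- paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    charToRaw(s)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  # tags in ascending order
  uid <- charToRaw("1.2.840.10008.1.2.1")
  if (length(uid) %% 2 == 1) uid <- c(uid, as.raw(0))
  elem(0x0002L, 0x0010L, "UI", uid)
  elem(0x0008L, 0x0060L, "CS", charToRaw("CT"))
  elem(0x0018L, 0x0050L, "DS", ds(slice_thickness))
  elem(0x0020L, 0x0013L, "IS", ds(instance))
  elem(0x0020L, 0x0032L, "DS", ds(c(0, 0, z)))
  elem(0x0028L, 0x0010L, "US", us(rows))
  elem(0x0028L, 0x0011L, "US", us(cols))
  elem(0x0028L, 0x0030L, "DS", ds(pixel_spacing))
  elem(0x0028L, 0x0100L, "US", us(16L))
  elem(0x0028L, 0x0103L, "US", us(if (signed) 1L else 0L))
  elem(0x0028L, 0x1052L, "DS", ds(intercept))
  elem(0x0028L, 0x1053L, "DS", ds(slope))
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  elem(0x7FE0L, 0x0010L, "OW", px)
  writeBin(rawConnectionValue(con), path)
  invisible(path)
}
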