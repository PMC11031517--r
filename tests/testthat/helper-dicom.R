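# Byte-level writer for minimal explicit-VR little-endian DICOM CT slices.
# Constructed independently of the package's reader (raw writeBin only).

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_elem <- function(group, elem, vr, value) {
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    body <- value
    c(head, as.raw(c(0, 0)), dcm_u32(length(body)), body)
  } else if (vr == "US") {
    body <- dcm_u16(value)
    c(head, dcm_u16(length(body)), body)
  } else {
    s <- as.character(value)
    if (length(s) > 1) s <- paste(s, collapse = "\\")
    body <- charToRaw(s)
    if (length(body) %% 2 == 1)
      body <- c(body, if (vr == "UI") as.raw(0) else charToRaw(" "))
    c(head, dcm_u16(length(body)), body)
  }
}

# pixels: integer matrix indexed [column(x), row(y)], stored row-major
write_test_dicom <- function(path, pixels, pos = c(0, 0, 0),
                             orient = c(1, 0, 0, 0, 1, 0),
                             pixel_spacing = c(1, 1),
                             slope = 1, intercept = -1024,
                             omit_rescale = FALSE) {
  stopifnot(is.matrix(pixels))
  cols <- nrow(pixels); rows <- ncol(pixels)
  stored <- as.integer(pixels)  # row-major stream: image columns (x) fastest
  px <- writeBin(stored, raw(), size = 2, endian = "little")
  out <- c(rep(as.raw(0), 128), charToRaw("DICM"),
           dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
           dcm_elem(0x0008, 0x0060, "CS", "CT"),
           dcm_elem(0x0020, 0x0032, "DS", format(pos)),
           dcm_elem(0x0020, 0x0037, "DS", format(orient)),
           dcm_elem(0x0028, 0x0010, "US", rows),
           dcm_elem(0x0028, 0x0011, "US", cols),
           dcm_elem(0x0028, 0x0030, "DS", format(pixel_spacing)),
           dcm_elem(0x0028, 0x0100, "US", 16),
           dcm_elem(0x0028, 0x0103, "US", 1))
  if (!omit_rescale)
    out <- c(out,
             dcm_elem(0x0028, 0x1052, "DS", format(intercept)),
             dcm_elem(0x0028, 0x1053, "DS", format(slope)))
  out <- c(out, dcm_elem(0x7FE0, 0x0010, "OW", px))
  writeBin(out, path)
  invisible(path)
}

write_test_dicom_series <- function(dir, slices, z0 = 0, dz = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(slices))
    write_test_dicom(file.path(dir, sprintf("slice%03d.dcm", i)),
                     slices[[i]], pos = c(0, 0, z0 + (i - 1) * dz), ...)
  invisible(dir)
}
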