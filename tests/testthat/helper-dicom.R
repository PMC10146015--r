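# Minimal DICOM writer for test fixtures: explicit or implicit VR
# little-endian, single-frame 8- or 16-bit grayscale.

.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.w32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dicom_element <- function(group, elem, vr, value_raw, explicit = TRUE) {
  len <- length(value_raw)
  if (len %% 2 == 1) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1
  }
  head <- c(.w16(group), .w16(elem))
  if (explicit) {
    if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
      head <- c(head, charToRaw(vr), as.raw(c(0, 0)), .w32(len))
    } else {
      head <- c(head, charToRaw(vr), .w16(len))
    }
  } else {
    head <- c(head, .w32(len))
  }
  c(head, value_raw)
}

write_test_dicom <- function(path, pixels, position = 0, spacing = c(0.5, 0.5),
                             bits = 16L, explicit = TRUE) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- c(
    .dicom_element(0x0002, 0x0002, "UI",
                   charToRaw("1.2.840.10008.5.1.4.1.1.4"), TRUE),
    .dicom_element(0x0002, 0x0010, "UI", charToRaw(ts), TRUE)
  )
  px <- as.integer(t(pixels)) # row-major
  px_raw <- writeBin(px, raw(), size = bits %/% 8L, endian = "little")
  ds <- c(
    .dicom_element(0x0020, 0x0032, "DS",
                   charToRaw(sprintf("0\\0\\%g", position)), explicit),
    .dicom_element(0x0020, 0x1041, "DS", charToRaw(sprintf("%g", position)),
                   explicit),
    .dicom_element(0x0028, 0x0010, "US", .w16(nrow(pixels)), explicit),
    .dicom_element(0x0028, 0x0011, "US", .w16(ncol(pixels)), explicit),
    .dicom_element(0x0028, 0x0030, "DS",
                   charToRaw(sprintf("%g\\%g", spacing[1], spacing[2])),
                   explicit),
    .dicom_element(0x0028, 0x0100, "US", .w16(bits), explicit),
    .dicom_element(0x0028, 0x0103, "US", .w16(0L), explicit),
    .dicom_element(0x7FE0, 0x0010, if (bits == 8) "OB" else "OW", px_raw,
                   explicit)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}
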