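# Minimal DICOM reader: explicit and implicit VR little-endian transfer
# syntaxes, uncompressed grayscale pixel data, the handful of tags the slice
# model needs. Compressed syntaxes and big-endian files are rejected.

.u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
.u32 <- function(raw, at) {
  as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
}

.LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UT", "UN", "UC", "UR")
.UNDEF_LEN <- 4294967295

# Skip an undefined-length value by scanning for the sequence delimitation
# item (FFFE,E0DD). Nested undefined-length sequences are rare in image
# objects; a flat scan suffices for the files this reader accepts.
.skip_undefined <- function(raw, pos) {
  pat <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
  n <- length(raw)
  while (pos + 7L <= n) {
    if (raw[pos] == pat[1] && raw[pos + 1L] == pat[2] &&
        raw[pos + 2L] == pat[3] && raw[pos + 3L] == pat[4]) {
      return(pos + 8L)
    }
    pos <- pos + 1L
  }
  stop("unterminated undefined-length sequence in DICOM stream", call. = FALSE)
}

.parse_ds <- function(bytes) {
  as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]])
}

read_dicom_slice <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) {
    stop(sprintf("unreadable DICOM file: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = n)
  if (rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("not a DICOM file (missing DICM marker): %s", path),
         call. = FALSE)
  }
  pos <- 133L
  tags <- new.env(parent = emptyenv())
  explicit <- TRUE
  ts_uid <- "1.2.840.10008.1.2.1"
  in_meta <- TRUE

  read_element <- function(pos, explicit) {
    group <- .u16(raw, pos)
    elem <- .u16(raw, pos + 2L)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- .u16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, pos)
      pos <- pos + 4L
    }
    list(group = group, elem = elem, vr = vr, len = len, value_at = pos)
  }

  while (pos + 7L <= length(raw)) {
    el <- read_element(pos, explicit = if (in_meta) TRUE else explicit)
    if (in_meta && el$group != 2L) {
      in_meta <- FALSE
      explicit <- ts_uid != "1.2.840.10008.1.2"
      if (!ts_uid %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        stop(sprintf("unsupported DICOM transfer syntax %s in %s", ts_uid,
                     path), call. = FALSE)
      }
      el <- read_element(pos, explicit = explicit)
    }
    if (el$len == .UNDEF_LEN) {
      pos <- .skip_undefined(raw, el$value_at)
      next
    }
    val_end <- el$value_at + el$len - 1L
    if (el$len > 0 && val_end > length(raw)) {
      stop(sprintf("truncated DICOM element in %s", path), call. = FALSE)
    }
    bytes <- if (el$len > 0) raw[el$value_at:val_end] else raw(0)
    key <- sprintf("%04x%04x", el$group, el$elem)
    if (key == "00020010") {
      ts_uid <- trimws(rawToChar(bytes[bytes != as.raw(0)]))
    } else if (key %in% c("00280010", "00280011", "00280100", "00280103")) {
      assign(key, .u16(bytes, 1L), envir = tags)
    } else if (key %in% c("00280030", "00201041", "00200032",
                          "00281052", "00281053")) {
      assign(key, .parse_ds(bytes), envir = tags)
    } else if (key == "7fe00010") {
      assign(key, bytes, envir = tags)
    }
    pos <- el$value_at + el$len
  }

  need <- function(key, what) {
    if (!exists(key, envir = tags)) {
      stop(sprintf("DICOM file %s is missing %s", path, what), call. = FALSE)
    }
    get(key, envir = tags)
  }
  rows <- need("00280010", "Rows")
  cols <- need("00280011", "Columns")
  bits <- if (exists("00280100", envir = tags)) get("00280100", envir = tags) else 16L
  signed <- exists("00280103", envir = tags) && get("00280103", envir = tags) == 1L
  px_bytes <- need("7fe00010", "PixelData")
  npx <- rows * cols
  pixels <- if (bits <= 8) {
    as.integer(px_bytes[seq_len(npx)])
  } else {
    readBin(px_bytes, "integer", n = npx, size = 2L, signed = signed,
            endian = "little")
  }
  if (exists("00281053", envir = tags) || exists("00281052", envir = tags)) {
    slope <- if (exists("00281053", envir = tags)) get("00281053", envir = tags) else 1
    icept <- if (exists("00281052", envir = tags)) get("00281052", envir = tags) else 0
    pixels <- pixels * slope + icept
  }
  position <- if (exists("00201041", envir = tags)) {
    get("00201041", envir = tags)[1]
  } else if (exists("00200032", envir = tags)) {
    get("00200032", envir = tags)[3]
  } else {
    NA_real_
  }
  spacing <- if (exists("00280030", envir = tags)) {
    get("00280030", envir = tags)[1:2]
  } else {
    c(1, 1)
  }
  list(pixels = matrix(pixels, nrow = rows, ncol = cols, byrow = TRUE),
       position = position, spacing = spacing)
}
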