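#' Construct a raw slice record
#'
#' A single 2-D slice of one MRI sequence before 8-bit normalization:
#' arbitrary-bit-depth non-negative scanner intensities together with the
#' acquisition geometry needed to pair slices across sequences.
#'
#' @param pixels non-negative numeric matrix (scanner arbitrary intensity).
#' @param slice_position_mm scalar position along the patient z axis, mm.
#' @param pixel_spacing_mm length-2 positive vector (row, col spacing, mm).
#' @param sequence_kind one of `"T2WI"`, `"ADC"`, `"DWI"`, or `NA` when not
#'   yet known.
#' @param source_id opaque provenance string (file name, series UID, ...).
#' @return an object of class `bpfuse_raw_slice`.
#' @export
raw_slice <- function(pixels, slice_position_mm, pixel_spacing_mm = c(1, 1),
                      sequence_kind = NA_character_, source_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    stop("pixels must be a non-empty matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("pixel values must be non-negative", call. = FALSE)
  }
  if (length(pixel_spacing_mm) != 2 || any(pixel_spacing_mm <= 0)) {
    stop("pixel_spacing_mm must be two positive values", call. = FALSE)
  }
  if (!is.na(sequence_kind) && !sequence_kind %in% c("T2WI", "ADC", "DWI")) {
    stop("sequence_kind must be one of T2WI, ADC, DWI", call. = FALSE)
  }
  structure(list(pixels = pixels,
                 slice_position_mm = as.numeric(slice_position_mm),
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 sequence_kind = sequence_kind,
                 source_id = as.character(source_id)),
            class = "bpfuse_raw_slice")
}

#' @export
print.bpfuse_raw_slice <- function(x, ...) {
  cat(sprintf("<bpfuse_raw_slice> %s %d x %d at z = %.2f mm (%s)\n",
              ifelse(is.na(x$sequence_kind), "?", x$sequence_kind),
              nrow(x$pixels), ncol(x$pixels), x$slice_position_mm,
              x$source_id))
  invisible(x)
}

.list_series_files <- function(path, exts) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(exts)) {
    files <- files[tolower(tools::file_ext(files)) %in% exts |
                     grepl("\\.nii\\.gz$", files)]
  }
  sort(files)
}

.read_png_gray <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3 &&
        !(all(img[, , 1] == img[, , 2]) && all(img[, , 2] == img[, , 3]))) {
      stop(sprintf("PNG slice is not grayscale: %s", file), call. = FALSE)
    }
    img <- img[, , 1]
  }
  u8_cast(img * 255)
}

.png_sidecar_geometry <- function(path, n) {
  sidecar <- file.path(path, "geometry.yaml")
  if (file.exists(sidecar)) {
    geo <- yaml::read_yaml(sidecar)
    positions <- if (!is.null(geo$slice_positions_mm)) {
      as.numeric(geo$slice_positions_mm)
    } else {
      origin <- if (!is.null(geo$origin_mm)) as.numeric(geo$origin_mm) else 0
      thick <- if (!is.null(geo$slice_thickness_mm)) as.numeric(geo$slice_thickness_mm) else 1
      origin + (seq_len(n) - 1) * thick
    }
    spacing <- if (!is.null(geo$pixel_spacing_mm)) {
      as.numeric(geo$pixel_spacing_mm)
    } else {
      c(1, 1)
    }
    if (length(positions) != n) {
      stop(sprintf("geometry sidecar lists %d positions for %d slices",
                   length(positions), n), call. = FALSE)
    }
    list(positions = positions, spacing = spacing)
  } else {
    warning("PNG series carries no geometry sidecar; using slice index as position with unit spacing",
            call. = FALSE)
    list(positions = seq_len(n) - 1, spacing = c(1, 1))
  }
}

#' Read an ordered series of slices from disk
#'
#' Supported inputs: a directory of single-frame DICOM files, a NIfTI-1
#' volume (`.nii` / `.nii.gz`), or a directory of 8-bit grayscale PNG slices.
#' PNG carries no geometry; an optional `geometry.yaml` sidecar in the
#' directory may supply `slice_positions_mm` (or `origin_mm` +
#' `slice_thickness_mm`) and `pixel_spacing_mm`, otherwise the slice index is
#' used as position with unit spacing and a warning is emitted.
#'
#' @param path directory (dicom, png) or volume file (nifti).
#' @param format one of `"dicom"`, `"nifti"`, `"png"`.
#' @param sequence_kind caller hint recorded on every returned slice.
#' @return list of [raw_slice()] objects sorted by `slice_position_mm`
#'   ascending.
#' @export
read_series <- function(path, format = c("dicom", "nifti", "png"),
                        sequence_kind = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("path does not exist: %s", path), call. = FALSE)
  }
  slices <- switch(format,
    dicom = {
      files <- .list_series_files(path, character(0))
      if (length(files) == 0) stop("no readable slices", call. = FALSE)
      lapply(files, function(f) {
        d <- read_dicom_slice(f)
        pos <- if (is.na(d$position)) match(f, files) - 1 else d$position
        raw_slice(d$pixels, pos, d$spacing, sequence_kind, basename(f))
      })
    },
    nifti = {
      vol <- RNifti::readNifti(path)
      arr <- as.array(vol)
      if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
      if (length(dim(arr)) != 3) {
        stop(sprintf("expected a 3-D NIfTI volume: %s", path), call. = FALSE)
      }
      pd <- attr(vol, "pixdim")
      if (is.null(pd) || length(pd) < 3) pd <- c(1, 1, 1)
      lapply(seq_len(dim(arr)[3]), function(k) {
        raw_slice(matrix(arr[, , k], dim(arr)[1], dim(arr)[2]),
                  (k - 1) * pd[3], pd[1:2], sequence_kind,
                  sprintf("%s#%d", basename(path), k))
      })
    },
    png = {
      files <- .list_series_files(path, "png")
      if (length(files) == 0) stop("no readable slices", call. = FALSE)
      geo <- .png_sidecar_geometry(path, length(files))
      lapply(seq_along(files), function(k) {
        raw_slice(.read_png_gray(files[k]), geo$positions[k], geo$spacing,
                  sequence_kind, basename(files[k]))
      })
    }
  )
  if (length(slices) == 0) stop("no readable slices", call. = FALSE)
  slices[order(vapply(slices, function(s) s$slice_position_mm, numeric(1)))]
}

#' Pair corresponding slices across the three sequences
#'
#' Greedy nearest-position matching with the T2WI series as the anatomical
#' reference: for each T2WI slice the closest unused ADC and DWI slices are
#' taken, and the triple is kept only if all three positions pairwise differ
#' by at most `tolerance_mm`. Every input slice is used at most once.
#'
#' @param t2_series,adc_series,dwi_series lists of [raw_slice()] sorted by
#'   position.
#' @param tolerance_mm non-negative pairing tolerance; the default is half
#'   the maximum accepted slice thickness of 3 mm.
#' @return list of lists with elements `t2`, `adc`, `dwi`; empty (with a
#'   warning) when no common slice level exists.
#' @export
pair_slices <- function(t2_series, adc_series, dwi_series,
                        tolerance_mm = 1.5) {
  stopifnot(tolerance_mm >= 0)
  pos <- function(series) vapply(series, function(s) s$slice_position_mm,
                                 numeric(1))
  adc_pos <- pos(adc_series)
  dwi_pos <- pos(dwi_series)
  adc_used <- rep(FALSE, length(adc_series))
  dwi_used <- rep(FALSE, length(dwi_series))
  out <- list()
  for (t2 in t2_series) {
    p <- t2$slice_position_mm
    ai <- which(!adc_used & abs(adc_pos - p) <= tolerance_mm)
    di <- which(!dwi_used & abs(dwi_pos - p) <= tolerance_mm)
    if (length(ai) == 0 || length(di) == 0) next
    ai <- ai[which.min(abs(adc_pos[ai] - p))]
    di <- di[which.min(abs(dwi_pos[di] - p))]
    if (abs(adc_pos[ai] - dwi_pos[di]) > tolerance_mm) next
    adc_used[ai] <- TRUE
    dwi_used[di] <- TRUE
    out[[length(out) + 1]] <- list(t2 = t2, adc = adc_series[[ai]],
                                   dwi = dwi_series[[di]])
  }
  if (length(out) == 0) {
    warning("no slice triples found within the pairing tolerance",
            call. = FALSE)
  }
  out
}

#' Normalize a raw slice to 8-bit grayscale
#'
#' `mode = "saturate"` reproduces a literal saturating integer cast: round
#' half away from zero, clip to \eqn{[0, 255]} -- appropriate for data that is
#' already display-windowed. `mode = "window"` (the default for raw scanner
#' data) linearly maps the `[low, high]` percentile range of the slice onto
#' \eqn{[0, 255]} before rounding and clipping, so 12/16-bit intensities are
#' not destroyed by the cast.
#'
#' @param raw a [raw_slice()].
#' @param mode `"window"` or `"saturate"`.
#' @param window_percentiles length-2 vector in \eqn{[0, 100]}.
#' @return integer matrix with values in \eqn{[0, 255]}.
#' @export
to_uint8 <- function(raw, mode = c("window", "saturate"),
                     window_percentiles = c(1, 99)) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "bpfuse_raw_slice"))
  px <- raw$pixels
  if (mode == "saturate") {
    return(u8_cast(px))
  }
  stopifnot(length(window_percentiles) == 2,
            all(window_percentiles >= 0), all(window_percentiles <= 100))
  qs <- stats::quantile(px, sort(window_percentiles) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    warning("degenerate window (constant slice); returning all-zero image",
            call. = FALSE)
    return(as_int_img(matrix(0L, nrow(px), ncol(px))))
  }
  u8_cast((px - qs[1]) / (qs[2] - qs[1]) * 255)
}

#' Write an 8-bit image to a lossless PNG
#'
#' @param img grayscale matrix or `h x w x 3` RGB array, values in
#'   \eqn{[0, 255]}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (anyNA(img) || any(img < 0) || any(img > 255)) {
    stop("img values must lie in [0, 255]", call. = FALSE)
  }
  ok <- tryCatch({
    png::writePNG(img / 255, target = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write image to %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read an 8-bit PNG back into a matrix or array
#'
#' @param path PNG file path.
#' @return integer matrix (grayscale) or `h x w x 3` integer array, values in
#'   \eqn{[0, 255]}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file does not exist: %s", path), call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  u8_cast(img * 255)
}

#' Read an integer label mask from PNG or NIfTI
#'
#' Labels follow the ground-truth convention: 0 background, 1 PI-RADS 3,
#' 2 PI-RADS 4, 3 PI-RADS 5, 4 extraprostatic tumor. PNG masks store the
#' label as the raw 8-bit pixel value.
#'
#' @param path file path (`.png`, `.nii`, `.nii.gz`).
#' @param slice for NIfTI volumes, which slice to extract (default 1).
#' @return integer matrix of labels.
#' @export
read_label_mask <- function(path, slice = 1L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- read_image(path)
  } else {
    arr <- as.array(RNifti::readNifti(path))
    m <- if (length(dim(arr)) == 3) arr[, , slice] else arr
    m <- round_half_away(m)
  }
  bad <- setdiff(unique(as.vector(m)), 0:4)
  if (length(bad)) {
    stop(sprintf("label mask %s contains invalid labels: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  as_int_img(matrix(as.integer(m), nrow(m), ncol(m)))
}
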