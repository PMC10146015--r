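#' Fusion configuration
#'
#' Parameters of the three-sequence fusion pipeline.
#'
#' @param out_size side length in pixels of the square working resolution all
#'   slices are resized to before fusion. Default 600.
#' @param interpolation resampling kernel for the resize step: `"bicubic"`
#'   (default, with antialiasing when shrinking), `"bilinear"` or `"nearest"`.
#' @param colormap_entries number of rows in the jet lookup table used for
#'   rendering, 256 (default) or 64. Affects only the rendered overlay, never
#'   the intensity mask.
#' @return an object of class `bpfuse_config`.
#' @export
fusion_config <- function(out_size = 600L,
                          interpolation = c("bicubic", "bilinear", "nearest"),
                          colormap_entries = 256L) {
  interpolation <- match.arg(interpolation)
  out_size <- as.integer(out_size)
  colormap_entries <- as.integer(colormap_entries)
  if (length(out_size) != 1 || is.na(out_size) || out_size < 1) {
    stop("out_size must be a positive integer", call. = FALSE)
  }
  if (!colormap_entries %in% c(64L, 256L)) {
    stop("colormap_entries must be 64 or 256", call. = FALSE)
  }
  structure(list(out_size = out_size, interpolation = interpolation,
                 colormap_entries = colormap_entries),
            class = "bpfuse_config")
}

#' Bundle three co-registered 8-bit slices into a triplet
#'
#' @param t2,adc,dwi numeric matrices with values in \eqn{[0, 255]} and
#'   identical dimensions: the T2-weighted slice, the apparent diffusion
#'   coefficient map and the high b-value diffusion-weighted slice.
#' @param slice_id opaque identifier carried through to outputs.
#' @return an object of class `bpfuse_triplet`.
#' @export
slice_triplet <- function(t2, adc, dwi, slice_id = "slice") {
  assert_gray8(t2, "t2")
  assert_gray8(adc, "adc")
  assert_gray8(dwi, "dwi")
  assert_same_dim(t2, adc, "T2WI", "ADC")
  assert_same_dim(t2, dwi, "T2WI", "DWI")
  structure(list(t2 = as_int_img(t2), adc = as_int_img(adc),
                 dwi = as_int_img(dwi), slice_id = as.character(slice_id)),
            class = "bpfuse_triplet")
}

#' @export
print.bpfuse_triplet <- function(x, ...) {
  cat(sprintf("<bpfuse_triplet> '%s' %d x %d\n", x$slice_id,
              nrow(x$t2), ncol(x$t2)))
  invisible(x)
}

#' Invert an 8-bit image
#'
#' T2WI and ADC are inverted before fusion so that suspicious tissue (dark on
#' both) carries high values, aligned with its appearance on DWI: each pixel
#' becomes `255 - value`.
#'
#' @param img numeric matrix with values in \eqn{[0, 255]}.
#' @return integer matrix of the same dimensions.
#' @export
invert <- function(img) {
  assert_gray8(img)
  as_int_img(255 - img)
}

#' Stack the three sequences into an RGB image
#'
#' Channel order is fixed: inverted T2WI in red, inverted ADC in green, DWI
#' (not inverted) in blue. A suspicious voxel -- dark T2WI, dark ADC, bright
#' DWI -- therefore maps near white.
#'
#' @param t2_inv,adc_inv,dwi numeric matrices in \eqn{[0, 255]} with identical
#'   dimensions.
#' @return integer array `h x w x 3`.
#' @export
stack_rgb <- function(t2_inv, adc_inv, dwi) {
  assert_gray8(t2_inv, "t2_inv")
  assert_gray8(adc_inv, "adc_inv")
  assert_gray8(dwi, "dwi")
  assert_same_dim(t2_inv, adc_inv, "inverted T2WI", "inverted ADC")
  assert_same_dim(t2_inv, dwi, "inverted T2WI", "DWI")
  out <- array(0L, dim = c(dim(t2_inv), 3))
  out[, , 1] <- t2_inv
  out[, , 2] <- adc_inv
  out[, , 3] <- dwi
  storage.mode(out) <- "integer"
  out
}

#' Extract the 8-bit luminance and the signed chroma channels
#'
#' The CIELAB lightness channel spans \eqn{[0, 100]} and is rescaled to 8-bit
#' by multiplying by 2.55 and casting with saturating round-half-away
#' semantics; the two chroma channels are passed through unmodified.
#'
#' @param lab a [rgb_to_lab()] result.
#' @return list with `luminance8` (integer matrix in \eqn{[0, 255]}), `alpha`
#'   and `beta` (numeric matrices, signed).
#' @export
extract_channels <- function(lab) {
  stopifnot(inherits(lab, "bpfuse_lab"))
  list(luminance8 = u8_cast(2.55 * lab$L), alpha = lab$a, beta = lab$b)
}

#' Chroma magnitude of the two color channels, cast to 8-bit
#'
#' Computes \eqn{\sqrt{\alpha^2 + \beta^2}} per pixel -- the CIELAB chroma --
#' and casts to 8-bit. The cast happens here, before the subtraction in
#' [intensity_mask()], preserving the integer-pipeline order of operations.
#'
#' @param alpha,beta signed numeric matrices of identical dimensions.
#' @return integer matrix in \eqn{[0, 255]}.
#' @export
combined_channels <- function(alpha, beta) {
  assert_same_dim(alpha, beta, "alpha", "beta")
  u8_cast(sqrt(alpha^2 + beta^2))
}

#' Tumor intensity mask
#'
#' Saturating 8-bit subtraction `max(0, luminance8 - combined)`: bright,
#' chromatically neutral pixels (the suspicious pattern after inversion and
#' stacking) keep high values; colorful pixels are suppressed by their chroma.
#'
#' @param luminance8 integer matrix in \eqn{[0, 255]}.
#' @param combined integer matrix in \eqn{[0, 255]} from
#'   [combined_channels()].
#' @return integer matrix in \eqn{[0, 255]}.
#' @export
intensity_mask <- function(luminance8, combined) {
  assert_gray8(luminance8, "luminance8")
  assert_gray8(combined, "combined")
  assert_same_dim(luminance8, combined, "luminance8", "combined")
  out <- luminance8 - combined
  out[out < 0] <- 0
  as_int_img(out)
}

#' Run the full fusion pipeline on a slice triplet
#'
#' Executes the six pipeline steps in order: (1) resize all three slices to
#' the working resolution, (2) invert T2WI and ADC, (3) stack into RGB,
#' (4) convert to CIELAB, (5) rescale luminance to 8-bit and take the chroma
#' channels, (6) compute the chroma magnitude, subtract it from the luminance
#' to obtain the tumor intensity mask, and render the mask through the jet
#' colormap. All intermediates are retained.
#'
#' @param triplet a [slice_triplet()].
#' @param cfg a [fusion_config()].
#' @return an object of class `bpfuse_result`: list with `t2_inv`, `adc_inv`,
#'   `rgb`, `lab`, `luminance8`, `combined`, `intensity`, `jet_rgb`,
#'   `slice_id` and the `cfg` used.
#' @examples
#' ph <- generate_phantom(phantom_spec(size = 64, noise_sigma = 0))
#' res <- fuse(ph$triplet, fusion_config(out_size = 64))
#' range(res$intensity)
#' @export
fuse <- function(triplet, cfg = fusion_config()) {
  stopifnot(inherits(triplet, "bpfuse_triplet"))
  t2 <- resize_to(triplet$t2, cfg)
  adc <- resize_to(triplet$adc, cfg)
  dwi <- resize_to(triplet$dwi, cfg)
  t2_inv <- invert(t2)
  adc_inv <- invert(adc)
  rgb <- stack_rgb(t2_inv, adc_inv, dwi)
  lab <- rgb_to_lab(rgb)
  ch <- extract_channels(lab)
  combined <- combined_channels(ch$alpha, ch$beta)
  intensity <- intensity_mask(ch$luminance8, combined)
  jet_rgb <- apply_jet(intensity, cfg)
  structure(list(t2_inv = t2_inv, adc_inv = adc_inv, rgb = rgb, lab = lab,
                 luminance8 = ch$luminance8, combined = combined,
                 intensity = intensity, jet_rgb = jet_rgb,
                 slice_id = triplet$slice_id, cfg = cfg),
            class = "bpfuse_result")
}

#' @export
print.bpfuse_result <- function(x, ...) {
  cat(sprintf("<bpfuse_result> '%s' %d x %d  intensity in [%d, %d], mean %.1f\n",
              x$slice_id, nrow(x$intensity), ncol(x$intensity),
              min(x$intensity), max(x$intensity), mean(x$intensity)))
  invisible(x)
}
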