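# Separable polyphase resize in the style of classic image-processing
# toolboxes: cubic (Keys, a = -0.5), triangle (bilinear) or box (nearest)
# kernel, with the kernel widened by the scale factor when shrinking
# (antialiasing). Output pixel centers are mapped into input space by
# x = (u - 0.5)/scale + 0.5, edges replicated.

kernel_cubic <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax <= 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

kernel_triangle <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 1 - ax, 0)
}

kernel_box <- function(x) (x >= -0.5 & x < 0.5) * 1

.resize_kernel <- function(interpolation) {
  switch(interpolation,
    bicubic = list(f = kernel_cubic, support = 4),
    bilinear = list(f = kernel_triangle, support = 2),
    nearest = list(f = kernel_box, support = 1),
    stop(sprintf("unknown interpolation '%s'", interpolation), call. = FALSE)
  )
}

# Dense out_len x in_len weight matrix for one dimension.
.resize_weights <- function(in_len, out_len, interpolation, antialias = TRUE) {
  k <- .resize_kernel(interpolation)
  scale <- out_len / in_len
  if (scale < 1 && antialias && interpolation != "nearest") {
    h <- function(x) scale * k$f(scale * x)
    kw <- k$support / scale
  } else {
    h <- k$f
    kw <- k$support
  }
  x <- (seq_len(out_len) - 0.5) / scale + 0.5
  left <- floor(x - kw / 2)
  p <- ceiling(kw) + 2
  ind <- outer(left, seq_len(p) - 1, "+")
  w <- h(x - ind)
  w <- w / rowSums(w)
  ind <- pmin(pmax(ind, 1), in_len)
  wm <- matrix(0, out_len, in_len)
  for (j in seq_len(p)) {
    wm[cbind(seq_len(out_len), ind[, j])] <-
      wm[cbind(seq_len(out_len), ind[, j])] + w[, j]
  }
  wm
}

resize_gray <- function(img, out_dim, interpolation = "bicubic",
                        antialias = TRUE) {
  wr <- .resize_weights(nrow(img), out_dim[1], interpolation, antialias)
  wc <- .resize_weights(ncol(img), out_dim[2], interpolation, antialias)
  wr %*% img %*% t(wc)
}

#' Resize an 8-bit grayscale slice to the working resolution
#'
#' The fusion algorithm operates on square slices of `cfg$out_size` pixels per
#' side (600 by default). Values are recomputed by separable convolution with
#' the configured kernel and cast back to 8-bit with saturating round-half-away
#' semantics.
#'
#' @param img numeric matrix with values in \eqn{[0, 255]}.
#' @param cfg a [fusion_config()] object.
#' @return integer matrix of dimension `out_size x out_size`, values in
#'   \eqn{[0, 255]}.
#' @seealso [fuse()] which applies this as its first step to all three
#'   sequences.
#' @export
resize_to <- function(img, cfg = fusion_config()) {
  assert_gray8(img)
  u8_cast(resize_gray(img, c(cfg$out_size, cfg$out_size), cfg$interpolation))
}
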