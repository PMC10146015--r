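# sRGB (IEC 61966-2-1) to CIELAB, D65 reference white. Implemented from the
# standard transform: inverse companding, linear RGB -> XYZ, XYZ -> Lab.
# The D65 white point (0.95047, 1, 1.08883) matches the row sums of the
# RGB -> XYZ matrix, so pure white maps to L = 100, a ~ 0, b ~ 0.

.srgb_to_xyz <- matrix(c(
  0.412456439089692, 0.357576077643909, 0.180437483266399,
  0.212672851405623, 0.715152155287818, 0.0721749699584796,
  0.0193338955823293, 0.119192025881303, 0.950304078536368
), nrow = 3, byrow = TRUE)

.d65_white <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

srgb_decompand <- function(u) {
  # u in [0, 1]
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Convert an 8-bit RGB image to CIELAB channels
#'
#' Assumes sRGB encoding with the D65 reference white, the convention of the
#' standard colorimetry transform. Returns the lightness channel `L` in
#' \eqn{[0, 100]} and the two signed chroma channels `a` (green--red axis) and
#' `b` (blue--yellow axis).
#'
#' @param rgb numeric array of dimension `h x w x 3` with values in
#'   \eqn{[0, 255]}.
#' @return An object of class `bpfuse_lab`: a list with matrices `L`, `a`,
#'   `b`, each of dimension `h x w`.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3)) # pure sRGB red
#' lab <- rgb_to_lab(px)
#' round(c(lab$L, lab$a, lab$b), 2)
#' @export
rgb_to_lab <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] == 3)) {
    stop("rgb must be an h x w x 3 array", call. = FALSE)
  }
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 255)) {
    stop("rgb values must lie in [0, 255]", call. = FALSE)
  }
  d <- dim(rgb)
  r <- srgb_decompand(matrix(rgb[, , 1], d[1], d[2]) / 255)
  g <- srgb_decompand(matrix(rgb[, , 2], d[1], d[2]) / 255)
  b <- srgb_decompand(matrix(rgb[, , 3], d[1], d[2]) / 255)
  m <- .srgb_to_xyz
  x <- m[1, 1] * r + m[1, 2] * g + m[1, 3] * b
  y <- m[2, 1] * r + m[2, 2] * g + m[2, 3] * b
  z <- m[3, 1] * r + m[3, 2] * g + m[3, 3] * b
  fx <- lab_f(x / .d65_white[["X"]])
  fy <- lab_f(y / .d65_white[["Y"]])
  fz <- lab_f(z / .d65_white[["Z"]])
  out <- list(
    L = 116 * fy - 16,
    a = 500 * (fx - fy),
    b = 200 * (fy - fz)
  )
  class(out) <- "bpfuse_lab"
  out
}

#' @export
print.bpfuse_lab <- function(x, ...) {
  d <- dim(x$L)
  cat(sprintf("<bpfuse_lab> %d x %d  L in [%.2f, %.2f], a in [%.2f, %.2f], b in [%.2f, %.2f]\n",
              d[1], d[2], min(x$L), max(x$L), min(x$a), max(x$a),
              min(x$b), max(x$b)))
  invisible(x)
}
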