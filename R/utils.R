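#' @keywords internal
"_PACKAGE"

# Saturating 8-bit cast used throughout the pipeline: round half away from
# zero, then clip to [0, 255]. Matches the semantics of a saturating integer
# cast so intermediate products stay bit-compatible with an integer pipeline.
u8_cast <- function(x) {
  out <- sign(x) * floor(abs(x) + 0.5)
  out[out < 0] <- 0
  out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

# Round half away from zero without clipping.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_gray8 <- function(img) {
  is.matrix(img) && is.numeric(img) &&
    !anyNA(img) && all(img >= 0) && all(img <= 255)
}

assert_gray8 <- function(img, what = "image") {
  if (!is_gray8(img)) {
    stop(sprintf("%s must be a numeric matrix with values in [0, 255]", what),
         call. = FALSE)
  }
  invisible(img)
}

assert_same_dim <- function(a, b, what_a = "first image", what_b = "second image") {
  da <- dim(a)[1:2]
  db <- dim(b)[1:2]
  if (!identical(da, db)) {
    stop(sprintf("dimension mismatch: %s is %dx%d but %s is %dx%d",
                 what_a, da[1], da[2], what_b, db[1], db[2]), call. = FALSE)
  }
  invisible(TRUE)
}

as_int_img <- function(img) {
  storage.mode(img) <- "integer"
  img
}
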