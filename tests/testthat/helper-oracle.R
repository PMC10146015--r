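# Straight-line scalar re-implementation of pipeline steps 2-6 (inversion,
# RGB stacking, sRGB -> Lab, luminance rescale, chroma magnitude, saturating
# subtraction), written with plain per-pixel loops and its own inline
# formulas. Used as the independent oracle for the production pipeline.

oracle_pixel_lab <- function(r8, g8, b8) {
  comp <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  r <- comp(r8); g <- comp(g8); b <- comp(b8)
  x <- 0.412456439089692 * r + 0.357576077643909 * g + 0.180437483266399 * b
  y <- 0.212672851405623 * r + 0.715152155287818 * g + 0.0721749699584796 * b
  z <- 0.0193338955823293 * r + 0.119192025881303 * g + 0.950304078536368 * b
  f <- function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }
  fx <- f(x / 0.95047); fy <- f(y / 1); fz <- f(z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

oracle_u8 <- function(v) {
  v <- sign(v) * floor(abs(v) + 0.5)
  max(0, min(255, v))
}

# steps 2-6 on an already-resized triplet; returns the intensity image
oracle_intensity <- function(t2, adc, dwi) {
  out <- matrix(0L, nrow(t2), ncol(t2))
  for (i in seq_len(nrow(t2))) {
    for (j in seq_len(ncol(t2))) {
      lab <- oracle_pixel_lab(255 - t2[i, j], 255 - adc[i, j], dwi[i, j])
      lum <- oracle_u8(2.55 * lab[["L"]])
      comb <- oracle_u8(sqrt(lab[["a"]]^2 + lab[["b"]]^2))
      out[i, j] <- as.integer(max(0, lum - comb))
    }
  }
  out
}

random_gray8 <- function(n, m = n) {
  matrix(sample(0:255, n * m, replace = TRUE), n, m)
}

random_triplet <- function(n = 32) {
  slice_triplet(random_gray8(n), random_gray8(n), random_gray8(n))
}

# Reference CIELAB triples for the sRGB corner colors, from the standard
# sRGB -> XYZ(D65) -> Lab transform, cross-checked against an independent
# colorimetry implementation before being frozen here.
lab_references <- list(
  red = list(rgb = c(255, 0, 0), lab = c(53.2406, 80.0923, 67.2028)),
  green = list(rgb = c(0, 255, 0), lab = c(87.7351, -86.1830, 83.1797)),
  blue = list(rgb = c(0, 0, 255), lab = c(32.2957, 79.1856, -107.8573)),
  mixed = list(rgb = c(200, 150, 30), lab = c(65.1120, 8.6333, 63.8018))
)

# Brute-force 8-connected components by repeated flood fill.
brute_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  next_lab <- 0L
  for (si in seq_len(nrow(mask))) {
    for (sj in seq_len(ncol(mask))) {
      if (!mask[si, sj] || lab[si, sj] != 0L) next
      next_lab <- next_lab + 1L
      queue <- list(c(si, sj))
      lab[si, sj] <- next_lab
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) {
          for (dj in -1:1) {
            ni <- p[1] + di; nj <- p[2] + dj
            if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
                mask[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- next_lab
              queue[[length(queue) + 1]] <- c(ni, nj)
            }
          }
        }
      }
    }
  }
  lab
}
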