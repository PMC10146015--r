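#' Jet colormap lookup table
#'
#' The classic blue -> cyan -> yellow -> red piecewise-linear pseudocolor
#' ramp. Entry 1 is dark blue, the last entry dark red.
#'
#' @param n number of entries, 64 or 256.
#' @return numeric matrix `n x 3` with RGB values in \eqn{[0, 1]}.
#' @export
jet_colormap <- function(n = 256) {
  if (!n %in% c(64L, 256L)) {
    stop("colormap_entries must be 64 or 256", call. = FALSE)
  }
  m <- ceiling(n / 4)
  u <- c(seq_len(m) / m, rep(1, m - 1), seq(m, 1) / m)
  g <- ceiling(m / 2) - (n %% 4 == 1) + seq_along(u)
  r <- g + m
  b <- g - m
  cm <- matrix(0, n, 3)
  keep <- r >= 1 & r <= n
  cm[r[keep], 1] <- u[keep]
  keep <- g >= 1 & g <= n
  cm[g[keep], 2] <- u[keep]
  keep <- b >= 1 & b <= n
  cm[b[keep], 3] <- u[keep]
  cm
}

#' Render an intensity mask through the jet colormap
#'
#' Pixel value `v` (0--255) selects entry `v + 1` of a 256-entry jet table,
#' the indexed-color convention for 8-bit images. With a 64-entry table the
#' value is first scaled by 64/256 and floored.
#'
#' @param intensity integer matrix with values in \eqn{[0, 255]}.
#' @param cfg a [fusion_config()]; `colormap_entries` selects the table size.
#' @return numeric array `h x w x 3` with values in \eqn{[0, 1]}.
#' @export
apply_jet <- function(intensity, cfg = fusion_config()) {
  assert_gray8(intensity, "intensity")
  n <- cfg$colormap_entries
  cm <- jet_colormap(n)
  idx <- as.integer(intensity)
  if (n == 64L) idx <- idx %/% 4L
  idx <- pmin(idx, n - 1L) + 1L
  d <- dim(intensity)
  array(cm[idx, ], dim = c(d[1], d[2], 3))
}
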