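.gray_to_rgb <- function(img) {
  array(rep(as.numeric(img), 3), dim = c(dim(img), 3))
}

#' Compose the six-panel fusion figure as one RGB image
#'
#' Layout (2 rows x 3 columns): T2WI, ADC, DWI on top; RGB fusion, grayscale
#' tumor intensity, jet-rendered intensity below. Built by pixel composition
#' (no graphics device), so outputs are byte-reproducible.
#'
#' @param result a [fuse()] result.
#' @param gap gutter width in pixels between panels.
#' @return integer RGB array in \eqn{[0, 255]}.
#' @export
fusion_panel <- function(result, gap = 4L) {
  stopifnot(inherits(result, "bpfuse_result"))
  panels <- list(
    .gray_to_rgb(invert(result$t2_inv)),
    .gray_to_rgb(invert(result$adc_inv)),
    .gray_to_rgb(result$rgb[, , 3]),
    result$rgb,
    .gray_to_rgb(result$intensity),
    u8_cast(result$jet_rgb * 255)
  )
  h <- dim(panels[[1]])[1]
  w <- dim(panels[[1]])[2]
  out <- array(255L, dim = c(2 * h + gap, 3 * w + 2 * gap, 3))
  for (k in seq_along(panels)) {
    row0 <- ((k - 1) %/% 3) * (h + gap)
    col0 <- ((k - 1) %% 3) * (w + gap)
    out[row0 + seq_len(h), col0 + seq_len(w), ] <- panels[[k]]
  }
  storage.mode(out) <- "integer"
  out
}

#' Plot per-class region histograms
#'
#' Intensity histograms of the fused mask over each ground-truth class, with
#' the conventional class colors: PI-RADS 3 yellow, PI-RADS 4 orange,
#' PI-RADS 5 red, extraprostatic black. Background (label 0) is dropped.
#'
#' @param hist a [region_histogram()] result.
#' @return a ggplot object.
#' @export
plot_region_histogram <- function(hist) {
  stopifnot(inherits(hist, "bpfuse_region_histogram"))
  df <- as.data.frame(hist)
  df <- df[df$label != 0 & df$count > 0, ]
  class_names <- c(`1` = "PI-RADS 3", `2` = "PI-RADS 4", `3` = "PI-RADS 5",
                   `4` = "extraprostatic")
  class_cols <- c("PI-RADS 3" = "#E6C700", "PI-RADS 4" = "#E67E00",
                  "PI-RADS 5" = "#CC0000", "extraprostatic" = "#000000")
  df$class <- factor(class_names[as.character(df$label)],
                     levels = class_names)
  ggplot2::ggplot(df, ggplot2::aes(x = intensity, y = count, fill = class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = class_cols, name = NULL) +
    ggplot2::facet_wrap(~class, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "fused intensity", y = "pixel count") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("intensity", "count", "class"))
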