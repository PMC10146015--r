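#' Evaluate an intensity mask against a ground-truth label mask
#'
#' For each tumor class (PI-RADS 3 / 4 / 5) the component-level detection
#' counts ([detection_accuracy()]) and the Dice overlap between the band
#' binarization and the ground-truth pixels of that class.
#'
#' @param intensity integer matrix in \eqn{[0, 255]}.
#' @param gt integer label matrix of identical dimensions.
#' @param bands a [threshold_bands()] object.
#' @param min_overlap_fraction see [detection_accuracy()].
#' @return data frame with one row per class: `class` (PI-RADS score),
#'   `label`, `band_lo`, `band_hi`, `detected`, `total`, `accuracy`, `dice`,
#'   `gt_pixels`, `mean_intensity` (mean fused intensity over the class's
#'   ground-truth pixels, `NA` when absent).
#' @export
evaluate_intensity <- function(intensity, gt, bands = threshold_bands(),
                               min_overlap_fraction = 0.25) {
  assert_same_dim(intensity, gt, "intensity", "label mask")
  rows <- lapply(1:3, function(lb) {
    band <- bands[[c("pr3", "pr4", "pr5")[lb]]]
    det <- detection_accuracy(intensity, gt, lb, bands, min_overlap_fraction)
    gt_px <- gt == lb
    data.frame(
      class = c(3L, 4L, 5L)[lb], label = lb,
      band_lo = band[1], band_hi = band[2],
      detected = det$detected, total = det$total, accuracy = det$accuracy,
      dice = dice(binarize_band(intensity, band), gt_px),
      gt_pixels = sum(gt_px),
      mean_intensity = if (any(gt_px)) mean(intensity[gt_px]) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Evaluate a phantom suite end to end
#'
#' Runs the fusion pipeline on every phantom at its native resolution (so the
#' label mask stays aligned) and aggregates per-class detection across the
#' suite.
#'
#' @param suite a [generate_suite()] result.
#' @param bands,min_overlap_fraction see [evaluate_intensity()].
#' @param cfg optional [fusion_config()]; defaults to the phantom size with
#'   nearest (identity) resampling.
#' @return list with `per_slice` (data frame, one row per phantom x class)
#'   and `summary` (data frame, per-class totals and pooled accuracy).
#' @export
evaluate_suite <- function(suite, bands = threshold_bands(),
                           min_overlap_fraction = 0.25, cfg = NULL) {
  per <- lapply(seq_along(suite), function(i) {
    ph <- suite[[i]]
    use_cfg <- if (is.null(cfg)) {
      fusion_config(out_size = ph$spec$size, interpolation = "nearest")
    } else {
      cfg
    }
    res <- fuse(ph$triplet, use_cfg)
    gt <- ph$label_mask
    if (!identical(dim(gt), dim(res$intensity))) {
      gt <- u8_cast(resize_gray(gt, dim(res$intensity), "nearest"))
    }
    ev <- evaluate_intensity(res$intensity, gt, bands, min_overlap_fraction)
    ev$phantom <- i
    ev$pattern <- if (is.null(ph$pattern)) NA_character_ else ph$pattern
    ev
  })
  per <- do.call(rbind, per)
  agg <- stats::aggregate(cbind(detected, total) ~ class, data = per, sum)
  agg$accuracy <- ifelse(agg$total > 0, agg$detected / agg$total, NA_real_)
  list(per_slice = per, summary = agg)
}
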