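#' PI-RADS intensity threshold bands
#'
#' Closed integer intervals on the fused intensity mask that separate the
#' three suspicion classes. The defaults are the empirical cut points
#' PI-RADS 3 \eqn{[100, 164]}, PI-RADS 4 \eqn{[165, 189]}, PI-RADS 5
#' \eqn{[190, 220]}. Intervals must be pairwise disjoint and ordered.
#'
#' @param pr3,pr4,pr5 length-2 integer vectors `c(lo, hi)`, bounds in
#'   \eqn{[0, 255]}.
#' @param extend_pr5 if `TRUE`, the PI-RADS 5 band upper bound is raised to
#'   255 so intensities above the printed band are still treated as very high
#'   risk.
#' @return an object of class `bpfuse_bands`.
#' @export
threshold_bands <- function(pr3 = c(100L, 164L), pr4 = c(165L, 189L),
                            pr5 = c(190L, 220L), extend_pr5 = FALSE) {
  bands <- list(pr3 = as.integer(pr3), pr4 = as.integer(pr4),
                pr5 = as.integer(pr5))
  if (extend_pr5) bands$pr5[2] <- 255L
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || anyNA(b) || b[1] > b[2] || b[1] < 0 || b[2] > 255) {
      stop(sprintf("band %s must be c(lo, hi) with 0 <= lo <= hi <= 255", nm),
           call. = FALSE)
    }
  }
  if (!(bands$pr3[2] < bands$pr4[1] && bands$pr4[2] < bands$pr5[1])) {
    stop("bands must be disjoint and ordered: pr3 < pr4 < pr5", call. = FALSE)
  }
  structure(bands, class = "bpfuse_bands")
}

#' @export
print.bpfuse_bands <- function(x, ...) {
  cat(sprintf("<bpfuse_bands> PI-RADS 3 [%d, %d]  PI-RADS 4 [%d, %d]  PI-RADS 5 [%d, %d]\n",
              x$pr3[1], x$pr3[2], x$pr4[1], x$pr4[2], x$pr5[1], x$pr5[2]))
  invisible(x)
}

#' Intersect two readers' label masks into a ground truth
#'
#' A pixel keeps its label only where both readers assigned the same nonzero
#' label; everywhere else it becomes background. Pixels where the readers
#' assigned different nonzero labels indicate an annotation error and are
#' counted in a warning.
#'
#' @param reader_a,reader_b integer label matrices of identical dimensions.
#' @return integer label matrix.
#' @export
intersect_masks <- function(reader_a, reader_b) {
  assert_same_dim(reader_a, reader_b, "reader A mask", "reader B mask")
  agree <- reader_a == reader_b & reader_a != 0
  conflict <- sum(reader_a != reader_b & reader_a != 0 & reader_b != 0)
  if (conflict > 0) {
    warning(sprintf("%d pixels carry conflicting nonzero labels; set to background",
                    conflict), call. = FALSE)
  }
  out <- matrix(0L, nrow(reader_a), ncol(reader_a))
  out[agree] <- as.integer(reader_a[agree])
  out
}

#' Binarize an intensity mask against one threshold band
#'
#' @param intensity integer matrix in \eqn{[0, 255]}.
#' @param band length-2 vector `c(lo, hi)`; both bounds inclusive.
#' @return logical matrix.
#' @export
binarize_band <- function(intensity, band) {
  assert_gray8(intensity, "intensity")
  stopifnot(length(band) == 2, band[1] <= band[2],
            band[1] >= 0, band[2] <= 255)
  intensity >= band[1] & intensity <= band[2]
}

#' Classify intensity pixels into PI-RADS bands
#'
#' Each pixel receives exactly one label: 1, 2 or 3 for membership in the
#' PI-RADS 3 / 4 / 5 band, 0 below the PI-RADS 3 floor or above the PI-RADS 5
#' ceiling. Label 4 (extraprostatic) is a ground-truth-only class and is never
#' produced.
#'
#' @param intensity integer matrix in \eqn{[0, 255]}.
#' @param bands a [threshold_bands()] object.
#' @return integer label matrix.
#' @export
classify_pixels <- function(intensity, bands = threshold_bands()) {
  assert_gray8(intensity, "intensity")
  stopifnot(inherits(bands, "bpfuse_bands"))
  out <- matrix(0L, nrow(intensity), ncol(intensity))
  out[binarize_band(intensity, bands$pr3)] <- 1L
  out[binarize_band(intensity, bands$pr4)] <- 2L
  out[binarize_band(intensity, bands$pr5)] <- 3L
  out
}

#' Per-label intensity histograms over a ground-truth segmentation
#'
#' For every label present in the mask, the 256-bin histogram (bin = intensity
#' value) of the fused intensity over that label's pixels.
#'
#' @param intensity integer matrix in \eqn{[0, 255]}.
#' @param gt integer label matrix of identical dimensions.
#' @return an object of class `bpfuse_region_histogram`: an integer matrix
#'   with one row per label present (row names are the label ids) and 256
#'   columns named `"0"`..`"255"`. Convert with [as.data.frame()] for a tidy
#'   long format.
#' @export
region_histogram <- function(intensity, gt) {
  assert_gray8(intensity, "intensity")
  assert_same_dim(intensity, gt, "intensity", "label mask")
  labels <- sort(unique(as.vector(gt)))
  counts <- t(vapply(labels, function(lb) {
    tabulate(as.integer(intensity[gt == lb]) + 1L, nbins = 256L)
  }, integer(256)))
  dimnames(counts) <- list(label = labels, intensity = 0:255)
  structure(counts, class = c("bpfuse_region_histogram", class(counts)))
}

#' @export
as.data.frame.bpfuse_region_histogram <- function(x, ...) {
  labels <- as.integer(rownames(x))
  data.frame(
    label = rep(labels, each = 256L),
    intensity = rep(0:255, times = length(labels)),
    count = as.integer(t(unclass(x)))
  )
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return scalar in \eqn{[0, 1]}.
#' @export
dice <- function(a, b) {
  assert_same_dim(a, b, "mask A", "mask B")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Label 8-connected components of a binary mask
#'
#' Diagonal contacts join components, the standard convention for 2-D lesion
#' blobs. Built on 4-connected labeling followed by union-find merging of
#' labels that touch diagonally.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 background, components numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  lab4 <- EBImage::bwlabel(mask * 1L)
  lab4 <- matrix(as.integer(lab4), nrow(mask), ncol(mask))
  nlab <- max(lab4)
  if (nlab <= 1) return(lab4)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab4); nc <- ncol(lab4)
  diag_pairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    unique(cbind(a[keep], b[keep]))
  }
  p1 <- diag_pairs(lab4[-nr, -nc], lab4[-1, -1])   # down-right neighbors
  p2 <- diag_pairs(lab4[-nr, -1], lab4[-1, -nc])   # down-left neighbors
  for (p in list(p1, p2)) {
    if (length(p)) for (k in seq_len(nrow(p))) union_(p[k, 1], p[k, 2])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  nz <- lab4 > 0
  out[nz] <- relab[lab4[nz]]
  out
}

#' Component-level lesion detection against a threshold band
#'
#' Ground-truth connected components (8-connectivity) of the target label are
#' enumerated; a component counts as detected when at least
#' `min_overlap_fraction` of its pixels fall inside the intensity band for
#' that label.
#'
#' @param intensity integer matrix in \eqn{[0, 255]}.
#' @param gt integer label matrix of identical dimensions.
#' @param target_label 1 (PI-RADS 3), 2 (PI-RADS 4) or 3 (PI-RADS 5).
#' @param bands a [threshold_bands()] object.
#' @param min_overlap_fraction fraction of component pixels that must light
#'   up in the band, in \eqn{(0, 1]}. Default 0.25: pixel-exact overlap is not
#'   expected because lesion edges are labeled imprecisely even by expert
#'   readers.
#' @return list with `detected`, `total` (component counts) and `accuracy`
#'   (`detected/total`, `NA` when no component exists).
#' @export
detection_accuracy <- function(intensity, gt, target_label,
                               bands = threshold_bands(),
                               min_overlap_fraction = 0.25) {
  stopifnot(target_label %in% 1:3,
            min_overlap_fraction > 0, min_overlap_fraction <= 1)
  assert_same_dim(intensity, gt, "intensity", "label mask")
  band <- bands[[c("pr3", "pr4", "pr5")[target_label]]]
  inband <- binarize_band(intensity, band)
  comp <- label_components(gt == target_label)
  total <- max(comp)
  if (total == 0) {
    return(list(detected = 0L, total = 0L, accuracy = NA_real_))
  }
  detected <- sum(vapply(seq_len(total), function(k) {
    mean(inband[comp == k]) >= min_overlap_fraction
  }, logical(1)))
  list(detected = as.integer(detected), total = as.integer(total),
       accuracy = detected / total)
}
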