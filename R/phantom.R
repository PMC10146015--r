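# Synthetic bpMRI phantom: an elliptical gland with a T2-bright peripheral
# zone and an intermediate, heterogeneous transition zone, plus disk lesions
# carrying the per-sequence signal patterns the fusion method assumes.
#
# The per-pattern signal constants below were calibrated once against the
# fusion pipeline (tools/calibrate_signal_model.R) so that the noiseless
# fused lesion means land where the threshold bands expect them
# (pr5 -> 205, inside [190, 220]; pr4 -> 176, inside [165, 189]) and then
# frozen. A transition-zone T2-only lesion cannot reach the PI-RADS 3 band:
# its luminance gain is cancelled by the chroma penalty, which is exactly the
# transition-zone insensitivity the method is known for.

.bg_signal <- list(
  outside = c(t2 = 40, adc = 130, dwi = 20),
  pz = c(t2 = 200, adc = 170, dwi = 60),
  tz = c(t2 = 130, adc = 150, dwi = 70)
)

.lesion_signal <- list(
  pr5 = c(t2 = 60, adc = 50, dwi = 210),
  pr4 = c(t2 = 90, adc = 80, dwi = 180),
  pr3_tz = c(t2 = 80, adc = 150, dwi = 70),
  extraprostatic = c(t2 = 60, adc = 50, dwi = 210),
  shine_through = c(t2 = 200, adc = 220, dwi = 220),
  prostatitis = c(t2 = 120, adc = 170, dwi = 140)
)

.pattern_label <- c(pr3_tz = 1L, pr4 = 2L, pr5 = 3L, extraprostatic = 4L,
                    shine_through = 0L, prostatitis = 0L)

#' Default per-sequence signal levels for a lesion pattern
#'
#' Mean 8-bit levels (T2WI, ADC, DWI) that a lesion of the given pattern is
#' rendered with. `pr5` is more extreme than `pr4` in all three sequences
#' (darker T2WI and ADC, brighter DWI); `shine_through` couples high DWI with
#' high ADC (no true diffusion restriction); `pr3_tz` differs from the
#' transition-zone background only on T2WI.
#'
#' @param pattern one of `"pr3_tz"`, `"pr4"`, `"pr5"`, `"extraprostatic"`,
#'   `"shine_through"`, `"prostatitis"`.
#' @return named numeric vector `c(t2, adc, dwi)`.
#' @export
default_signal_model <- function(pattern) {
  if (!pattern %in% names(.lesion_signal)) {
    stop(sprintf("unknown lesion pattern '%s'", pattern), call. = FALSE)
  }
  .lesion_signal[[pattern]]
}

#' Describe one synthetic lesion
#'
#' @param center length-2 vector, pixel coordinates (row, col) of the lesion
#'   center.
#' @param radius disk radius in pixels, at least 2.
#' @param pattern lesion pattern, see [default_signal_model()].
#' @param signal_levels optional override of the per-sequence means
#'   `c(t2, adc, dwi)` in \eqn{[0, 255]}.
#' @return an object of class `bpfuse_lesion`.
#' @export
lesion_spec <- function(center, radius, pattern,
                        signal_levels = default_signal_model(pattern)) {
  if (!pattern %in% names(.lesion_signal)) {
    stop(sprintf("unknown lesion pattern '%s'", pattern), call. = FALSE)
  }
  stopifnot(length(center) == 2, radius >= 2,
            length(signal_levels) == 3,
            all(signal_levels >= 0), all(signal_levels <= 255))
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 pattern = pattern,
                 signal_levels = stats::setNames(as.numeric(signal_levels),
                                                 c("t2", "adc", "dwi"))),
            class = "bpfuse_lesion")
}

#' Describe a synthetic bpMRI slice phantom
#'
#' @param size square image side in pixels (default 256, the pre-resize
#'   working size).
#' @param gland_center,gland_semiaxes ellipse of the prostate gland in pixel
#'   units; defaults scale with `size`.
#' @param tz_fraction transition zone semi-axes as a fraction of the gland
#'   semi-axes (concentric inner ellipse).
#' @param lesions list of [lesion_spec()] objects; lesions must lie fully
#'   inside the image and must not overlap.
#' @param noise_sigma standard deviation of the additive zero-mean Gaussian
#'   noise, in 8-bit units (applied per sequence, then clipped).
#' @param seed integer seed making the phantom fully reproducible.
#' @return an object of class `bpfuse_phantom_spec`.
#' @export
phantom_spec <- function(size = 256L, gland_center = NULL,
                         gland_semiaxes = NULL, tz_fraction = 0.55,
                         lesions = list(), noise_sigma = 8, seed = 1L) {
  size <- as.integer(size)
  stopifnot(size >= 16, noise_sigma >= 0, tz_fraction > 0, tz_fraction < 1)
  if (is.null(gland_center)) gland_center <- c(size, size) * 0.5
  if (is.null(gland_semiaxes)) gland_semiaxes <- c(0.36, 0.28) * size
  stopifnot(all(gland_semiaxes > 0))
  for (les in lesions) {
    stopifnot(inherits(les, "bpfuse_lesion"))
    if (any(les$center - les$radius < 1) ||
        any(les$center + les$radius > size)) {
      stop("lesions must lie fully inside the image", call. = FALSE)
    }
  }
  if (length(lesions) > 1) {
    for (i in seq_len(length(lesions) - 1)) {
      for (j in seq(i + 1, length(lesions))) {
        d <- sqrt(sum((lesions[[i]]$center - lesions[[j]]$center)^2))
        if (d < lesions[[i]]$radius + lesions[[j]]$radius) {
          stop(sprintf("lesions %d and %d overlap; ground truth would be ambiguous",
                       i, j), call. = FALSE)
        }
      }
    }
  }
  structure(list(size = size, gland_center = as.numeric(gland_center),
                 gland_semiaxes = as.numeric(gland_semiaxes),
                 tz_fraction = tz_fraction, lesions = lesions,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "bpfuse_phantom_spec")
}

.ellipse_mask <- function(size, center, semiaxes) {
  r <- matrix(seq_len(size), size, size)
  c_ <- t(r)
  ((r - center[1]) / semiaxes[1])^2 + ((c_ - center[2]) / semiaxes[2])^2 <= 1
}

.disk_mask <- function(size, center, radius) {
  r <- matrix(seq_len(size), size, size)
  c_ <- t(r)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

# Smooth low-frequency field in [-1, 1] for transition-zone heterogeneity.
.smooth_field <- function(size) {
  coef <- stats::rnorm(6)
  x <- seq(0, 2 * pi, length.out = size)
  f <- outer(coef[1] * sin(2 * x) + coef[2] * cos(3 * x),
             coef[3] * sin(3 * x) + coef[4] * cos(2 * x)) +
    outer(coef[5] * sin(x), coef[6] * cos(x))
  f / max(abs(f), 1e-12)
}

#' Generate a synthetic bpMRI slice triplet with ground truth
#'
#' Renders the gland (T2-bright peripheral zone, intermediate heterogeneous
#' transition zone), stamps each lesion as a filled disk with its
#' per-sequence signal levels, adds clipped zero-mean Gaussian noise, and
#' builds the label mask: PI-RADS 3 / 4 / 5 and extraprostatic lesions get
#' labels 1--4; the confounder patterns (`shine_through`, `prostatitis`)
#' remain background label 0 because they are not tumor ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `triplet` (a [slice_triplet()]), `label_mask` (integer
#'   matrix) and `spec`.
#' @examples
#' sp <- phantom_spec(size = 96, noise_sigma = 0, lesions = list(
#'   lesion_spec(c(48, 70), 8, "pr5")))
#' ph <- generate_phantom(sp)
#' table(ph$label_mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "bpfuse_phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  size <- spec$size
  gland <- .ellipse_mask(size, spec$gland_center, spec$gland_semiaxes)
  tz <- .ellipse_mask(size, spec$gland_center,
                      spec$gland_semiaxes * spec$tz_fraction)
  pz <- gland & !tz

  chans <- list()
  for (ch in c("t2", "adc", "dwi")) {
    img <- matrix(.bg_signal$outside[[ch]], size, size)
    img[pz] <- .bg_signal$pz[[ch]]
    img[tz] <- .bg_signal$tz[[ch]]
    chans[[ch]] <- img
  }
  # heterogeneous transition-zone texture on T2WI
  het <- .smooth_field(size)
  chans$t2[tz] <- chans$t2[tz] + 10 * het[tz]

  labels <- matrix(0L, size, size)
  for (les in spec$lesions) {
    disk <- .disk_mask(size, les$center, les$radius)
    for (ch in c("t2", "adc", "dwi")) {
      chans[[ch]][disk] <- les$signal_levels[[ch]]
    }
    lb <- .pattern_label[[les$pattern]]
    if (lb > 0L) labels[disk] <- lb
  }

  for (ch in c("t2", "adc", "dwi")) {
    if (spec$noise_sigma > 0) {
      chans[[ch]] <- chans[[ch]] +
        stats::rnorm(size * size, sd = spec$noise_sigma)
    }
    chans[[ch]] <- u8_cast(chans[[ch]])
  }

  list(triplet = slice_triplet(chans$t2, chans$adc, chans$dwi,
                               slice_id = sprintf("phantom-seed%d", spec$seed)),
       label_mask = labels, spec = spec)
}

#' Generate a balanced suite of single-lesion phantoms
#'
#' One phantom per pattern per repeat, with lesion size and position varied
#' deterministically from the seed: peripheral-zone patterns are placed at a
#' random angle inside the peripheral zone, `pr3_tz` inside the transition
#' zone, `extraprostatic` outside the gland.
#'
#' @param n_per_pattern phantoms per pattern, at least 1.
#' @param seed master seed; each phantom derives its own sub-seed.
#' @param size,noise_sigma forwarded to [phantom_spec()].
#' @param patterns patterns to cover (default all six).
#' @return list of [generate_phantom()] results, length
#'   `n_per_pattern * length(patterns)`.
#' @export
generate_suite <- function(n_per_pattern, seed = 1L, size = 256L,
                           noise_sigma = 8,
                           patterns = names(.lesion_signal)) {
  stopifnot(n_per_pattern >= 1)
  size <- as.integer(size)
  center <- c(size, size) * 0.5
  semi <- c(0.36, 0.28) * size
  out <- vector("list", n_per_pattern * length(patterns))
  idx <- 0L
  for (pat in patterns) {
    for (k in seq_len(n_per_pattern)) {
      idx <- idx + 1L
      sub_seed <- (seed + 7919L * idx) %% .Machine$integer.max
      # placement drawn from the sub-seed, then the phantom re-seeds itself
      old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv(), inherits = FALSE)
      } else {
        NULL
      }
      set.seed(sub_seed + 1L)
      radius <- stats::runif(1, max(4, 0.03 * size), max(6, 0.06 * size))
      theta <- stats::runif(1, 0, 2 * pi)
      pos <- switch(pat,
        pr3_tz = center + 0.45 * semi * spec_dir(theta) * 0.55,
        extraprostatic = center +
          (semi + radius + 4) * spec_dir(theta) * 1.08,
        center + 0.78 * semi * spec_dir(theta)
      )
      pos[1] <- min(max(pos[1], radius + 2), size - radius - 1)
      pos[2] <- min(max(pos[2], radius + 2), size - radius - 1)
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      sp <- phantom_spec(size = size, lesions = list(
        lesion_spec(pos, radius, pat)), noise_sigma = noise_sigma,
        seed = sub_seed)
      out[[idx]] <- generate_phantom(sp)
      out[[idx]]$pattern <- pat
    }
  }
  out
}

spec_dir <- function(theta) c(cos(theta), sin(theta))
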