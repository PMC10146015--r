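---
title: "Methods: bpMRI fusion, threshold-band classification, and the phantom model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bpMRI fusion, threshold-band classification, and the phantom model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpfuse)
```

## The model and its assumptions

`bpfuse` scores every pixel of an axial prostate slice by how well it
matches the multi-sequence signature of clinically significant cancer:
hypointense on T2WI, hypointense on the ADC map, hyperintense on high
b-value DWI. After inverting T2WI and ADC, that signature becomes *bright on
all three channels*. Stacking the three images as RGB and moving to CIELAB
separates how bright a pixel is (lightness `L`) from how discordant the
three sequences are (chroma `a*`, `b*`). The fused intensity

```
I = max(0, uint8(2.55 L) − uint8(sqrt(a*^2 + b*^2)))
```

is therefore high only where the sequences agree on suspicion. The chroma
subtraction is what rejects T2 shine-through: bright DWI with bright ADC is
a strongly colored pixel (low concordance), and its chroma wipes out its
lightness. With the default signal model, a shine-through region fuses to a
mean intensity of essentially 0, versus ≈ 201 for a PI-RADS 5 pattern.

The method assumes the three series are scanner-aligned axial obliques of
equal slice thickness (≤ 3 mm) with no inter-slice gap mismatch; there is no
registration step. It uses per-pixel intensity only — no shape, texture or
contrast-enhancement features.

## Input normalization

Clinical DICOM/NIfTI data carry 12–16-bit intensities. A literal saturating
8-bit cast would clip everything above 255, so `to_uint8()` defaults to
**percentile windowing**: the [1, 99] percentile range of each slice is
mapped linearly onto [0, 255]. The `saturate` mode reproduces the literal
cast and is appropriate only for data already display-windowed to 8 bits
(it is what the PNG pathway and the phantoms use). Whether a clinical ADC
map should first be clipped at a physical diffusion ceiling is
vendor-dependent and out of scope; windowing is this package's choice of a
sensible default, not a property of the fusion algorithm.

Slices are paired across sequences by position along the patient axis:
greedy nearest-neighbor matching with T2WI as the anatomical reference, a
pairwise tolerance of 1.5 mm (half the maximum accepted slice thickness),
and no slice reuse. Note that on a regular 3 mm grid *some* neighbor always
lies within 1.5 mm, so an offset series pairs to the nearest level rather
than failing; tighten `tolerance_mm` to demand closer alignment. PNG series
carry no geometry; a `geometry.yaml` sidecar can supply positions and
spacing, otherwise the slice index is used and a warning is emitted.

## Numerical conventions

* **Rounding**: every 8-bit cast rounds half away from zero, then clips to
  [0, 255] (`u8_cast`), matching saturating integer-cast semantics. Note
  that the convention applies to the *computed double*: `2.55 * 50` is
  127.49999999999999 in IEEE arithmetic and casts to 127, not 128.
* **Order of casts**: the chroma magnitude is cast to 8-bit *before* the
  subtraction from the 8-bit luminance, and the subtraction saturates at 0.
  Keeping this integer-pipeline order makes the output reproducible
  bit-for-bit by a scalar per-pixel re-implementation (the test suite
  asserts exact equality on random triplets).
* **Color space**: RGB→Lab assumes sRGB companding and the D65 reference
  white, implemented from the standard matrix (the white point equals the
  matrix row sums, so white maps to `L = 100` exactly up to the 4th
  decimal). `grDevices::convertColor` was not used because it deviates from
  the canonical transform by ~0.24 in `L` for saturated primaries.
* **Resize**: separable bicubic (Keys, a = −0.5) with kernel widening when
  shrinking (antialiasing), edges replicated; `bilinear` and `nearest` are
  available. Interpolation weights are normalized, so constants are
  preserved exactly. No installed package provides a bicubic filter, so it
  is implemented in-package.
* **Jet colormap**: the classic piecewise-linear blue→cyan→yellow→red
  table. Table length is configurable (256 default, 64 optional; a 64-entry
  table indexes `floor(v·64/256)`). The choice affects rendering only,
  never the intensity mask.
* **Degenerate inputs**: a constant slice under percentile windowing has an
  empty window and returns an all-zero image with a warning; an empty
  pairing result is a warning plus an empty output, not an error; Dice of
  two empty masks is defined as 1; detection accuracy over zero components
  is `NA`.

## Classification and evaluation

`classify_pixels()` applies the three closed intensity bands
(PI-RADS 3 [100, 164], PI-RADS 4 [165, 189], PI-RADS 5 [190, 220]); values
below 100 or above 220 are background. Intensities above 220 plausibly
relate to extraprostatic invasion but no classification rule is defined for
them, so they default to label 0; `threshold_bands(extend_pr5 = TRUE)`
extends the PI-RADS 5 band to 255 instead.

Ground truth is the label-wise intersection of two readers' masks; pixels
with conflicting nonzero labels indicate annotation errors and are set to
background with a warning. Detection is scored per 8-connected ground-truth
component (8-connectivity is the standard convention for 2-D lesion blobs):
a component is detected when at least `min_overlap_fraction` (default 0.25)
of its pixels fall in its class band. A pixel-exact criterion would be
meaningless given that even expert readers disagree on lesion edges, so the
component criterion is deliberately lenient and the Dice coefficient is
reported alongside as the pixel-level complement.

## The phantom model

`generate_phantom()` renders a 256 × 256 slice (default): an elliptical
gland with a T2-bright peripheral zone, a concentric intermediate
transition zone with smooth heterogeneous T2 texture (amplitude 10), a dark
extra-glandular background, disk lesions, and additive zero-mean Gaussian
noise (default σ = 8 in 8-bit units) clipped to [0, 255]. Disks and
Gaussian noise are deliberate simplifications: the method uses per-pixel
intensity only, so lesion shape realism, bias fields, Rician noise tails
and k-space artifacts would not change what the tests measure — they do
mean that passing phantom tests shows algorithmic correctness, not clinical
performance.

The six lesion patterns and their frozen per-sequence means (T2, ADC, DWI):

| pattern | levels | fused mean (no noise) |
|---|---|---|
| `pr5` | 60, 50, 210 | 205 |
| `pr4` | 90, 80, 180 | 176 |
| `pr3_tz` | 80, TZ, TZ | 91 |
| `shine_through` | 200, 220, 220 | 0 |
| `prostatitis` | 120, 170, 140 | 74 |
| `extraprostatic` | 60, 50, 210 (outside gland) | 205 |

These constants are calibration constants, not measurements: they were
chosen once, by running candidate levels through the pipeline
(`tools/calibrate_signal_model.R`) so that the pr5 and pr4 fused means land
mid-band, and then frozen. Two properties of the fusion surfaced during
that one-time calibration and shaped the defaults:

* **The score is not globally monotone in DWI.** Once the blue channel
  overshoots the inverted T2/ADC channels (DWI ≳ 215 against inverted
  levels ≈ 195–205), the pixel turns bluish and chroma rises again. The pr5
  default DWI is 210, and the monotonicity checks use ladders ending at the
  defaults (DWI 130→210, ADC 130→50, T2 140→60, step 20), the regime the
  signature describes.
* **A T2-only transition-zone lesion cannot reach the PI-RADS 3 band.**
  Lowering T2 alone raises the red channel, and the chroma penalty cancels
  the luminance gain almost exactly (fused mean ≈ 91 against a zone
  background of ≈ 93). This is not a calibration failure; it reproduces the
  method's documented insensitivity to equivocal transition-zone lesions,
  which are outside its intended use.

## Problem sizes

The test suite runs phantoms at 64–128 px and random triplets at 32 px;
the end-to-end detection check and the acceptance script use 20-phantom
suites at 256 px with noise σ = 8, scored with the printed bands and
`min_overlap_fraction = 0.25`. These sizes keep the full suite under ten
seconds on one CPU while leaving every disk lesion tens to hundreds of
pixels in area, large against a 1-px rasterization edge.

## Known limitations

* No registration: misaligned series degrade the fusion silently (within
  the pairing tolerance).
* The threshold bands are empirical constants from one scanner and one
  windowing platform; on differently windowed data they need re-derivation.
* PI-RADS 3 sensitivity is structurally poor (see above); the tool targets
  PI-RADS 4/5 and extraprostatic highlights.
* The DICOM reader is deliberately minimal: little-endian uncompressed
  single-frame grayscale only.
* Perceptual quality of the jet overlay is not evaluated by any test; only
  the underlying intensity mask is.
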