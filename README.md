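# bpfuse

Fusion of the three biparametric prostate MRI (bpMRI) sequences — T2-weighted
imaging (T2WI), the apparent diffusion coefficient map (ADC), and high
b-value diffusion-weighted imaging (DWI) — into a single grayscale
**tumor-intensity mask** that highlights lesions with a high or very high
risk of being clinically significant prostate cancer, for radiologists and
imaging researchers who want a reproducible "first-opinion" overlay and a
quantitative way to evaluate it against expert segmentations.

## The method

Prostate cancer follows a characteristic multi-sequence signature: the more
suspicious a lesion, the **darker** it is on T2WI and ADC (restricted
diffusion, low T2 signal) and the **brighter** it is on high b-value DWI.
The pipeline turns that concordance into one scalar per pixel:

1. resize each slice to a common square working resolution (600 × 600,
   8-bit grayscale);
2. invert T2WI and ADC: `T2' = 255 − T2`, `ADC' = 255 − ADC`, so suspicion
   is high-valued on all three channels;
3. stack into an RGB image: `R = T2'`, `G = ADC'`, `B = DWI`;
4. convert to CIELAB (sRGB encoding, D65 white): lightness `L ∈ [0, 100]`
   and signed chroma axes `a*`, `b*`;
5. rescale lightness to 8-bit: `L₈ = uint8(2.55 · L)`;
6. compute the chroma magnitude `C = uint8(√(a*² + b*²))` and the intensity
   mask `I = max(0, L₈ − C)`, rendered through a jet colormap for display.

A truly suspicious voxel (dark T2WI + dark ADC + bright DWI) maps near
**white** in step 3 — high lightness, near-zero chroma — so `I` is large.
Discordant patterns stay colorful and are suppressed by the chroma term. In
particular **T2 shine-through** (bright DWI *with* bright ADC, i.e. no true
diffusion restriction) maps to a saturated color and scores near zero.

Empirical intensity bands on `I` separate the PI-RADS suspicion classes:

| class | band on `I` |
|---|---|
| PI-RADS 3 | [100, 164] |
| PI-RADS 4 | [165, 189] |
| PI-RADS 5 | [190, 220] |

The package also provides slice I/O (DICOM / NIfTI-1 / PNG) with
position-based cross-sequence pairing, dual-reader label-mask intersection,
per-class region histograms, Dice overlap, component-level lesion detection,
and a seeded synthetic phantom generator so the whole pipeline is testable
without clinical data.

## Worked example

Generate a phantom slice with one PI-RADS 5-pattern lesion, fuse it, and
score the result against the phantom's ground truth:

```r
library(bpfuse)

sp  <- phantom_spec(size = 128, noise_sigma = 8, seed = 42,
                    lesions = list(lesion_spec(c(40, 88), 9, "pr5")))
ph  <- generate_phantom(sp)
res <- fuse(ph$triplet, fusion_config(out_size = 128, interpolation = "nearest"))
res
#> <bpfuse_result> 'phantom-seed42' 128 x 128  intensity in [43, 219], mean 83.5

evaluate_intensity(res$intensity, ph$label_mask)
#>   class label band_lo band_hi detected total accuracy      dice gt_pixels mean_intensity
#> 1     3     1     100     164        0     0       NA 0.0000000         0             NA
#> 2     4     2     165     189        0     0       NA 0.0000000         0             NA
#> 3     5     3     190     220        1     1        1 0.9631148       253       200.6601
```

The lesion's 253 ground-truth pixels average intensity ≈ 201, inside the
PI-RADS 5 band [190, 220]; the lesion component is detected (accuracy 1)
with a Dice of 0.96 between the band binarization and the ground truth.
`fusion_panel(res)` composes the six-panel overview (T2WI, ADC, DWI, RGB
fusion, intensity mask, jet overlay) as one writable image, and
`plot_region_histogram(region_histogram(res$intensity, ph$label_mask))`
draws the per-class intensity histograms.

A shell entry point wrapping the same functions ships in `inst/cli/bpfuse`
with subcommands `fuse`, `evaluate` and `phantom`.

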