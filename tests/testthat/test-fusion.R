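test_that("resize is exact for identity and constants, and preserves the mean under upsampling", {
  set.seed(2)
  img <- random_gray8(600)
  cfg <- fusion_config(out_size = 600, interpolation = "nearest")
  expect_identical(resize_to(img, cfg), as_int <- {
    storage.mode(img) <- "integer"; img
  })

  const <- matrix(77, 37, 61)
  for (interp in c("bicubic", "bilinear", "nearest")) {
    out <- resize_to(const, fusion_config(out_size = 600,
                                          interpolation = interp))
    expect_identical(dim(out), c(600L, 600L))
    expect_true(all(out == 77L))
  }

  checker <- 255 * outer(1:96, 1:96, function(i, j) (i + j) %% 2)
  up <- resize_to(checker, fusion_config(out_size = 600))
  expect_lt(abs(mean(up) - mean(checker)), 1)
})

test_that("invert is 255 minus the pixel and an involution", {
  expect_identical(invert(matrix(0, 1, 1)), matrix(255L, 1, 1))
  expect_identical(invert(matrix(255, 1, 1)), matrix(0L, 1, 1))
  set.seed(9)
  img <- random_gray8(25)
  expect_equal(invert(invert(img)), img, ignore_attr = TRUE)
})

test_that("stack_rgb assembles channels in (inverted T2, inverted ADC, DWI) order", {
  w <- matrix(255, 4, 4)
  z <- matrix(0, 4, 4)
  white <- stack_rgb(w, w, w)
  expect_true(all(white == 255L))
  red <- stack_rgb(w, z, z)
  expect_true(all(red[, , 1] == 255L) && all(red[, , 2:3] == 0L))
  expect_error(stack_rgb(w, z, matrix(0, 4, 5)), "DWI")
})

test_that("rgb_to_lab reproduces the colorimetry references", {
  px <- function(rgb) array(rgb, c(1, 1, 3))
  white <- rgb_to_lab(px(c(255, 255, 255)))
  expect_equal(white$L[1, 1], 100, tolerance = 1e-2)
  expect_lt(abs(white$a[1, 1]), 1e-2)
  expect_lt(abs(white$b[1, 1]), 1e-2)
  black <- rgb_to_lab(px(c(0, 0, 0)))
  expect_true(all(abs(c(black$L, black$a, black$b)) < 1e-2))
  for (ref in lab_references) {
    got <- rgb_to_lab(px(ref$rgb))
    expect_lt(max(abs(unname(c(got$L, got$a, got$b)) - ref$lab)), 0.1)
  }
})

test_that("extract_channels rescales luminance by 2.55 with round-half-away casting", {
  lab <- rgb_to_lab(array(c(255, 255, 255), c(1, 1, 3)))
  lab$L <- matrix(c(100, 0, 50, 39.4), 2, 2)
  lab$a <- matrix(0, 2, 2)
  lab$b <- matrix(0, 2, 2)
  ch <- extract_channels(lab)
  # the double product 2.55 * 50 sits just below 127.5, so it casts to 127
  expect_identical(as.vector(ch$luminance8), c(255L, 0L, 127L, 100L))
  # an exact half rounds away from zero: 127.5 -> 128
  half <- raw_slice(matrix(127.5, 1, 1), 0)
  expect_identical(as.vector(to_uint8(half, "saturate")), 128L)
  expect_identical(ch$alpha, lab$a)
})

test_that("combined_channels is the 8-bit chroma magnitude", {
  m <- function(v) matrix(v, 1, 1)
  expect_identical(combined_channels(m(0), m(0)), matrix(0L, 1, 1))
  expect_identical(combined_channels(m(3), m(4)), matrix(5L, 1, 1))
  expect_identical(combined_channels(m(-80), m(60)), matrix(100L, 1, 1))
  set.seed(4)
  a <- matrix(runif(100, -120, 120), 10, 10)
  b <- matrix(runif(100, -120, 120), 10, 10)
  got <- combined_channels(a, b)
  for (k in seq_along(a)) {
    expect_identical(got[k], as.integer(oracle_u8(sqrt(a[k]^2 + b[k]^2))))
  }
})

test_that("intensity_mask saturates at zero and equals luminance for neutral inputs", {
  m <- function(v) matrix(v, 1, 1)
  expect_identical(intensity_mask(m(200), m(50)), matrix(150L, 1, 1))
  expect_identical(intensity_mask(m(30), m(90)), matrix(0L, 1, 1))

  # equal R = G = B pixelwise -> zero chroma -> intensity == luminance8
  set.seed(15)
  g <- random_gray8(20)
  rgb <- stack_rgb(g, g, g)
  lab <- rgb_to_lab(rgb)
  ch <- extract_channels(lab)
  comb <- combined_channels(ch$alpha, ch$beta)
  expect_true(all(comb == 0L))
  expect_identical(intensity_mask(ch$luminance8, comb), ch$luminance8)
})

test_that("jet colormap endpoints and midpoint follow the piecewise-linear ramps", {
  cm <- jet_colormap(256)
  expect_equal(cm[1, ], c(0, 0, 0.515625))
  expect_equal(cm[256, ], c(0.5, 0, 0))
  v <- function(val, entries = 256L) {
    apply_jet(matrix(val, 1, 1), fusion_config(colormap_entries = entries))[1, 1, ]
  }
  expect_equal(v(0), cm[1, ])
  expect_equal(v(255), cm[256, ])
  expect_gt(v(128)[2], 0.95) # cyan-yellow transition: green near max
  cm64 <- jet_colormap(64)
  expect_equal(v(255, 64L), cm64[64, ])
  expect_equal(v(128, 64L), cm64[33, ]) # floor(128 * 64/256) = 32 (0-based)
})

test_that("fuse retains all intermediates and is spatially invariant on constant input", {
  g <- matrix(128, 24, 24)
  res <- fuse(slice_triplet(g, g, g), fusion_config(out_size = 24))
  expect_s3_class(res, "bpfuse_result")
  expect_length(unique(as.vector(res$intensity)), 1)
  expect_true(all(res$intensity <= res$luminance8))
})

test_that("a restricted-diffusion lesion fuses brighter than the gland background", {
  sp <- phantom_spec(size = 128, noise_sigma = 0, lesions = list(
    lesion_spec(c(40, 88), 9, "pr5")))
  ph <- generate_phantom(sp)
  res <- fuse(ph$triplet, fusion_config(out_size = 128,
                                        interpolation = "nearest"))
  lesion <- ph$label_mask == 3L
  expect_gt(mean(res$intensity[lesion]), mean(res$intensity[!lesion]))
})

test_that("the production pipeline matches the scalar per-pixel oracle bit for bit", {
  set.seed(33)
  cfg <- fusion_config(out_size = 32, interpolation = "nearest")
  for (rep in 1:5) {
    tr <- random_triplet(32)
    res <- fuse(tr, cfg)
    expect_identical(res$intensity, oracle_intensity(tr$t2, tr$adc, tr$dwi))
  }
})

test_that("intensity never exceeds the 8-bit luminance", {
  set.seed(44)
  for (rep in 1:5) {
    tr <- random_triplet(16)
    res <- fuse(tr, fusion_config(out_size = 16, interpolation = "nearest"))
    expect_true(all(res$intensity <= res$luminance8))
  }
})
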