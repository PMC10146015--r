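test_that("PNG series are read in position order, with and without geometry sidecar", {
  dir <- withr::local_tempdir()
  set.seed(11)
  imgs <- lapply(1:3, function(i) random_gray8(20))
  for (i in 1:3) {
    bpfuse::write_image(imgs[[i]], file.path(dir, sprintf("s%d.png", i)))
  }
  writeLines(c("slice_positions_mm: [6.0, 0.0, 3.0]",
               "pixel_spacing_mm: [0.5, 0.5]"),
             file.path(dir, "geometry.yaml"))
  series <- read_series(dir, "png", sequence_kind = "T2WI")
  expect_length(series, 3)
  expect_equal(vapply(series, `[[`, numeric(1), "slice_position_mm"),
               c(0, 3, 6))
  # sidecar positions permute the files: s2.png is at 0 mm
  expect_identical(series[[1]]$pixels, imgs[[2]])
  expect_identical(series[[1]]$pixel_spacing_mm, c(0.5, 0.5))
  expect_identical(series[[1]]$sequence_kind, "T2WI")

  file.remove(file.path(dir, "geometry.yaml"))
  expect_warning(series2 <- read_series(dir, "png"), "sidecar")
  expect_equal(vapply(series2, `[[`, numeric(1), "slice_position_mm"), 0:2)
})

test_that("empty directories and missing paths are I/O errors", {
  dir <- withr::local_tempdir()
  expect_error(read_series(dir, "png"), "no readable slices")
  expect_error(read_series(dir, "dicom"), "no readable slices")
  expect_error(read_series(file.path(dir, "nope"), "png"), "does not exist")
})

test_that("NIfTI volumes round-trip through write and read_series", {
  set.seed(7)
  vol <- array(sample(0:255, 24 * 20 * 16, replace = TRUE),
               dim = c(24, 20, 16))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  series <- read_series(f, "nifti", sequence_kind = "ADC")
  expect_length(series, 16)
  expect_identical(dim(series[[1]]$pixels), c(24L, 20L))
  for (k in 1:16) {
    expect_equal(unname(series[[k]]$pixels), vol[, , k],
                 ignore_attr = TRUE)
  }
  expect_equal(vapply(series, `[[`, numeric(1), "slice_position_mm"), 0:15)
})

test_that("DICOM series are parsed, sorted by position, and validated", {
  dir <- withr::local_tempdir()
  set.seed(3)
  positions <- c(9, 0, 3, 6) # written out of order
  slices <- lapply(positions, function(p) {
    matrix(sample(0:4000, 16 * 16, replace = TRUE), 16, 16)
  })
  for (i in seq_along(positions)) {
    write_test_dicom(file.path(dir, sprintf("im%d.dcm", i)), slices[[i]],
                     position = positions[i], spacing = c(0.7, 0.8))
  }
  series <- read_series(dir, "dicom", sequence_kind = "DWI")
  expect_length(series, 4)
  expect_equal(vapply(series, `[[`, numeric(1), "slice_position_mm"),
               c(0, 3, 6, 9))
  expect_identical(series[[1]]$pixels, slices[[2]])
  expect_equal(series[[1]]$pixel_spacing_mm, c(0.7, 0.8))

  # implicit VR and 8-bit pixel data
  dir2 <- withr::local_tempdir()
  px8 <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  write_test_dicom(file.path(dir2, "a.dcm"), px8, position = 1.5,
                   bits = 8L, explicit = FALSE)
  s2 <- read_series(dir2, "dicom")
  expect_identical(s2[[1]]$pixels, px8)
  expect_equal(s2[[1]]$slice_position_mm, 1.5)

  # corrupt file names the offender
  bad <- file.path(dir, "broken.dcm")
  writeBin(as.raw(rep(1, 200)), bad)
  expect_error(read_series(dir, "dicom"), "broken.dcm")
})

test_that("pair_slices matches aligned grids exactly and respects the tolerance", {
  mk <- function(positions, kind) {
    lapply(positions, function(p) {
      raw_slice(matrix(1, 4, 4), p, sequence_kind = kind)
    })
  }
  aligned <- pair_slices(mk(c(0, 3, 6), "T2WI"), mk(c(0, 3, 6), "ADC"),
                         mk(c(0, 3, 6), "DWI"), tolerance_mm = 0.5)
  expect_length(aligned, 3)

  # every cross-sequence distance exceeds the tolerance: nothing pairs
  expect_warning(
    none <- pair_slices(mk(c(0, 3, 6), "T2WI"), mk(c(0, 3, 6) + 1.6, "ADC"),
                        mk(c(0, 3, 6), "DWI"), tolerance_mm = 0.75),
    "no slice triples"
  )
  expect_length(none, 0)

  # an offset smaller than the tolerance pairs each T2 slice to its nearest
  # ADC neighbor, which may sit on the previous grid level
  offset <- pair_slices(mk(c(0, 3, 6), "T2WI"), mk(c(0, 3, 6) + 1.6, "ADC"),
                        mk(c(0, 3, 6), "DWI"), tolerance_mm = 1.5)
  expect_length(offset, 2)
  expect_equal(vapply(offset, function(tr) tr$adc$slice_position_mm,
                      numeric(1)), c(1.6, 4.6))
})

test_that("greedy pairing with an offset series uses every slice once and equals optimal assignment", {
  mk <- function(positions, kind) {
    lapply(seq_along(positions), function(i) {
      raw_slice(matrix(1, 4, 4), positions[i], sequence_kind = kind,
                source_id = sprintf("%s%d", kind, i))
    })
  }
  t2_pos <- seq(0, 21, by = 3)
  adc_pos <- t2_pos + 1.0
  triples <- pair_slices(mk(t2_pos, "T2WI"), mk(adc_pos, "ADC"),
                         mk(t2_pos, "DWI"), tolerance_mm = 1.5)
  expect_length(triples, length(t2_pos))
  adc_ids <- vapply(triples, function(tr) tr$adc$source_id, character(1))
  expect_length(unique(adc_ids), length(adc_ids)) # no reuse
  # each triple honors the tolerance pairwise
  for (tr in triples) {
    ps <- c(tr$t2$slice_position_mm, tr$adc$slice_position_mm,
            tr$dwi$slice_position_mm)
    expect_lte(max(dist(ps)), 1.5)
  }
  # brute-force optimal assignment of T2 to ADC slices yields the same count
  n <- length(t2_pos)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- max(vapply(perms(seq_len(min(n, 6))), function(p) {
    sum(abs(t2_pos[seq_along(p)] - adc_pos[p]) <= 1.5)
  }, numeric(1)))
  greedy6 <- sum(vapply(triples, function(tr) {
    tr$t2$slice_position_mm <= t2_pos[6]
  }, logical(1)))
  expect_equal(greedy6, best)
})

test_that("to_uint8 saturate clips and rounds; window maps percentile range onto [0, 255]", {
  rs <- raw_slice(matrix(c(300, 128, -0, 255.5), 2, 2), 0)
  out <- to_uint8(rs, "saturate")
  expect_identical(as.vector(out), c(255L, 128L, 0L, 255L))

  expect_warning(
    z <- to_uint8(raw_slice(matrix(500, 5, 5), 0), "window",
                  window_percentiles = c(1, 99)),
    "degenerate window"
  )
  expect_true(all(z == 0L))

  vals <- matrix(0:1023, 32, 32)
  w <- to_uint8(raw_slice(vals, 0), "window", window_percentiles = c(0, 100))
  expect_identical(range(w), c(0L, 255L))
  # closed-form linear map checked per pixel
  expect_identical(w, u8_ref <- {
    e <- vals / 1023 * 255
    matrix(as.integer(pmin(255, floor(e + 0.5))), 32, 32)
  })
})

test_that("to_uint8 preserves within-slice intensity ordering in both modes", {
  set.seed(21)
  px <- matrix(runif(400, 0, 4096), 20, 20)
  rs <- raw_slice(px, 0)
  for (mode in c("saturate", "window")) {
    out <- to_uint8(rs, mode)
    ord <- order(px)
    expect_true(all(diff(out[ord]) >= 0))
  }
})

test_that("write_image round-trips grayscale and RGB PNGs losslessly", {
  set.seed(5)
  gray <- random_gray8(40)
  rgb <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), c(40, 40, 3))
  fg <- withr::local_tempfile(fileext = ".png")
  fc <- withr::local_tempfile(fileext = ".png")
  write_image(gray, fg)
  write_image(rgb, fc)
  expect_identical(read_image(fg), as_int <- {
    storage.mode(gray) <- "integer"; gray
  })
  back <- read_image(fc)
  expect_identical(dim(back), dim(rgb))
  expect_true(all(back == rgb))
  expect_error(write_image(gray, file.path(tempdir(), "no/such/dir/x.png")),
               "cannot write")
})

test_that("label masks round-trip through PNG and reject invalid labels", {
  lm <- matrix(0L, 10, 10)
  lm[2:4, 2:4] <- 3L
  lm[7:8, 7:8] <- 4L
  f <- withr::local_tempfile(fileext = ".png")
  write_image(lm, f)
  expect_identical(read_label_mask(f), lm)
  bad <- matrix(9L, 4, 4)
  fb <- withr::local_tempfile(fileext = ".png")
  write_image(bad, fb)
  expect_error(read_label_mask(fb), "invalid labels")
})
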