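test_that("square-root transform maps the 16-bit range onto [0, 255]", {
  m <- matrix(c(0L, 1L, 4L, 65025L, 65535L, 10000L), 2, 3)
  out <- sqrt_to_8bit(m)
  expect_identical(out, matrix(c(0L, 1L, 2L, 255L, 255L, 100L), 2, 3))
  # monotone non-decreasing in the input
  set.seed(7)
  v <- sort(sample(0:65535, 500))
  tv <- as.vector(sqrt_to_8bit(matrix(v, 1)))
  expect_true(all(diff(tv) >= 0))
  expect_error(sqrt_to_8bit(matrix(-1, 2, 2)), "0, 65535")
  expect_error(sqrt_to_8bit(matrix(65536, 2, 2)), "0, 65535")
})

test_that("Gaussian smoothing preserves constants and total mass", {
  const <- matrix(7.5, 20, 30)
  expect_equal(smooth_gaussian(const), const, tolerance = 1e-12)
  # single interior bright pixel: symmetric blob, mass preserved
  img <- matrix(0, 21, 21)
  img[11, 11] <- 100
  sm <- smooth_gaussian(img)
  expect_equal(sum(sm), 100, tolerance = 1e-9)
  expect_equal(sm, sm[21:1, ], tolerance = 1e-12)
  expect_equal(sm, t(sm), tolerance = 1e-12)
  # direct kernel-sum oracle at the centre: k(0)^2 * amplitude
  k <- exp(-(-2:2)^2 / 2)
  k <- k / sum(k)
  expect_equal(sm[11, 11], 100 * k[3]^2, tolerance = 1e-12)
})

test_that("top-hat removes constants and is offset-invariant", {
  const <- matrix(42, 40, 40)
  expect_equal(tophat(const, 5), matrix(0, 40, 40), tolerance = 1e-12)
  set.seed(3)
  img <- matrix(runif(40 * 40, 0, 50), 40, 40)
  expect_equal(tophat(img + 17, 5), tophat(img, 5), tolerance = 1e-10)
  expect_true(all(tophat(img, 5) >= -1e-12))
  expect_error(tophat(matrix(0, 8, 8), 10), "too large")
})

test_that("top-hat matches the brute-force erosion/dilation oracle", {
  set.seed(11)
  for (radius in c(2, 4)) {
    img <- matrix(sample(0:80, 32 * 32, replace = TRUE), 32, 32)
    expect_equal(tophat(img, radius), tophat_oracle(img, radius),
                 tolerance = 1e-12)
  }
  # single narrow punctum on a flat background survives with background removed
  img <- matrix(10, 32, 32)
  img[15:17, 20:22] <- img[15:17, 20:22] + c(40, 60, 40, 60, 90, 60, 40, 60, 40)
  th <- tophat(img, 5)
  expect_equal(th, tophat_oracle(img, 5), tolerance = 1e-12)
  expect_equal(th[16, 21], 90, tolerance = 1e-12)
  expect_equal(sum(th > 0), 9)
})

test_that("NMS handles trivial cases and the threshold boundary", {
  cfg <- pipeline_config()
  expect_identical(nrow(find_peaks_nms(matrix(0, 16, 16), cfg)), 0L)
  img <- matrix(0, 16, 16)
  img[5, 9] <- 21
  expect_equal(unname(find_peaks_nms(img, cfg)), matrix(c(5L, 9L), 1))
  img[5, 9] <- 20   # threshold is inclusive
  expect_identical(nrow(find_peaks_nms(img, cfg)), 1L)
  img[5, 9] <- 19.5
  expect_identical(nrow(find_peaks_nms(img, cfg)), 0L)
})

test_that("NMS equals the exhaustive oracle on random images, plateaus included", {
  cfg <- pipeline_config(nms_threshold = 30)
  set.seed(42)
  for (i in 1:15) {
    # coarse values force plateau ties
    img <- matrix(sample(0:50, 48 * 48, replace = TRUE), 48, 48)
    expect_identical(unname(find_peaks_nms(img, cfg)),
                     nms_oracle(img, 3, 30))
  }
})

test_that("raising the NMS threshold never increases the peak count", {
  f <- generate_field(field_spec(seed = 31))
  img8 <- sqrt_to_8bit(f)
  enhanced <- tophat(tophat(smooth_gaussian(img8), 30), 5)
  counts <- vapply(c(5, 10, 20, 40, 80, 160), function(t) {
    nrow(find_peaks_nms(enhanced, pipeline_config(nms_threshold = t)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed assigns each isolated blob to its peak (flood-fill oracle)", {
  cfg <- pipeline_config()
  img <- matrix(0, 32, 32)
  for (r in 1:32) for (c in 1:32) {
    img[r, c] <- 100 * exp(-((r - 16)^2 + (c - 10)^2) / 8)
  }
  pk <- find_peaks_nms(img, cfg)
  expect_identical(nrow(pk), 1L)
  lab <- segment_puncta_watershed(img, pk, cfg)
  # oracle: the 8-connected component of >= threshold pixels containing the peak
  expect_identical(unname(lab == 1L), unname(img >= cfg$nms_threshold))
  # two well-separated blobs -> two disjoint regions containing their peaks
  img2 <- img
  for (r in 1:32) for (c in 1:32) {
    img2[r, c] <- img2[r, c] + 80 * exp(-((r - 8)^2 + (c - 25)^2) / 6)
  }
  pk2 <- find_peaks_nms(img2, cfg)
  expect_identical(nrow(pk2), 2L)
  lab2 <- segment_puncta_watershed(img2, pk2, cfg)
  expect_identical(lab2[pk2], c(1L, 2L))
  expect_identical(unname(lab2 > 0), unname(img2 >= cfg$nms_threshold))
  # zero peaks -> zero regions
  empty <- segment_puncta_watershed(img, matrix(integer(0), 0, 2), cfg)
  expect_true(all(empty == 0L))
})

test_that("puncta measurement equals the direct pixel-sum oracle", {
  labels <- matrix(0L, 8, 8)
  labels[2:3, 2:3] <- 1L
  img <- matrix(10L, 8, 8)
  rec <- measure_puncta(labels, img)
  expect_identical(rec$area_px, 4L)
  expect_equal(rec$mean_intensity, 10)
  expect_equal(rec$integrated_intensity, 40)
  # random labelling: integrated == sum over region, mean * area == integrated
  set.seed(5)
  labels <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  img <- matrix(sample(0:255, 64), 8, 8)
  rec <- measure_puncta(labels, img)
  for (i in seq_len(nrow(rec))) {
    expect_equal(rec$integrated_intensity[i],
                 sum(img[labels == rec$label[i]]))
    expect_equal(rec$mean_intensity[i] * rec$area_px[i],
                 rec$integrated_intensity[i])
  }
  expect_identical(nrow(measure_puncta(matrix(0L, 4, 4), matrix(0L, 4, 4))), 0L)
  expect_error(measure_puncta(matrix(0L, 4, 4), matrix(0L, 4, 5)), "same shape")
})

test_that("Otsu threshold separates a bimodal image and matches the oracle", {
  img <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_identical(t, otsu_oracle(img))
  expect_true(t >= 10 && t < 200)
  mask <- segment_cells(img)
  expect_identical(unname(mask$foreground), unname(img > t))
  expect_identical(mask$foreground_area_px, 50L)
  expect_error(otsu_threshold(matrix(7L, 5, 5)), "degenerate")
})

test_that("cell segmentation fills holes and keeps the largest component", {
  img <- matrix(10L, 40, 40)
  img[5:20, 5:20] <- 200L     # big blob
  img[10:13, 10:13] <- 10L    # interior hole
  img[30:33, 30:33] <- 200L   # smaller blob
  mask <- segment_cells(img)
  expect_true(all(mask$foreground[10:13, 10:13]))   # hole filled
  expect_false(any(mask$foreground[30:33, 30:33]))  # small blob dropped
  expect_identical(mask$foreground_area_px, 16L * 16L)
})

test_that("pipeline configuration is validated", {
  expect_error(pipeline_config(nms_threshold = 300), "0, 255")
  expect_error(pipeline_config(tophat_small_radius_px = 30,
                               tophat_large_radius_px = 30), "smaller")
})
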