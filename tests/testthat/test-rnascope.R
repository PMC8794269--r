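test_that("ROI measurement sums pixel values inside the polygon", {
  img <- matrix(0.5, 40, 40)
  poly <- cbind(c(5, 15, 15, 5), c(5, 5, 25, 25))
  m <- measure_roi(img, poly)
  expect_equal(m$area_px, 10 * 20)
  expect_equal(m$integrated_intensity, 0.5 * 200, tolerance = 1e-12)
  # polygon fully outside is an error
  out <- cbind(c(100, 110, 110, 100), c(100, 100, 110, 110))
  expect_error(measure_roi(img, out), "does not cover")
})

test_that("ROI measurement agrees with the generator ledger", {
  spec <- spot_fixture_spec(seed = 23, noise_sd = 0)
  img <- generate_spot_image(spec)
  m <- measure_roi(img$image, spec$roi_polygons$low, label = "low")
  led <- img$ledger[img$ledger$region == "low", ]
  expected <- 0.1 * m$area_px + sum(led$intensity)
  # Gaussian tails truncated at the ROI boundary cost well under 1%
  expect_equal(m$integrated_intensity, expected, tolerance = 0.01)
})

test_that("background level is intensive and accurate", {
  img <- matrix(0.37, 60, 60)
  small <- measure_roi(img, cbind(c(2, 12, 12, 2), c(2, 2, 12, 12)))
  large <- measure_roi(img, cbind(c(2, 42, 42, 2), c(2, 2, 42, 42)))
  expect_equal(background_level(small), 0.37, tolerance = 1e-12)
  expect_equal(background_level(large), background_level(small),
               tolerance = 1e-12)
  # on a noisy image the estimate is within 2 sd / sqrt(n) of truth
  set.seed(42)
  noisy <- matrix(0.2 + rnorm(300 * 300, 0, 0.05), 300, 300)
  big <- measure_roi(noisy, cbind(c(5, 295, 295, 5), c(5, 5, 295, 295)))
  expect_lt(abs(background_level(big) - 0.2),
            2 * 0.05 / sqrt(big$area_px))
})

test_that("mean dot intensity implements the background-corrected average", {
  bg_roi <- data.frame(label = "bg", integrated_intensity = 100, area_px = 1000)
  # 20 identical dots with corrected intensity I = 7 each
  dots <- data.frame(intensity = 7 + 0.1 * 30, area = 30)[rep(1, 20), ]
  cal <- dot_calibration(dots, bg_roi)
  expect_equal(mean_dot_intensity(cal), 7, tolerance = 1e-12)
  # zero background: plain arithmetic mean of raw intensities
  zero_bg <- data.frame(label = "bg", integrated_intensity = 0, area_px = 1000)
  cal0 <- dot_calibration(data.frame(intensity = c(4, 6, 8), area = 30), zero_bg)
  expect_equal(mean_dot_intensity(cal0), 6, tolerance = 1e-12)
  # dots dimmer than background is a calibration failure
  dim_dots <- data.frame(intensity = 1, area = 100)[rep(1, 5), ]
  expect_error(mean_dot_intensity(dot_calibration(dim_dots, bg_roi)),
               "calibration failure")
  # ledger oracle: recovered mean within 5% of a * 2 pi sigma^2
  spec <- spot_fixture_spec(seed = 31)
  img <- generate_spot_image(spec)
  led <- img$ledger[img$ledger$region == "calibration", ]
  bg <- measure_roi(img$image, spec$roi_polygons$background)
  cal_g <- dot_calibration(data.frame(intensity = led$intensity_raw,
                                      area = led$area), bg)
  expect_equal(mean_dot_intensity(cal_g), 2 * pi * 1.5^2, tolerance = 0.05)
})

test_that("dot counts pass negatives through and scale as pure ratios", {
  roi <- data.frame(label = "r", integrated_intensity = 95, area_px = 1000)
  d <- dots_in_roi(roi, background = 0.1, dot_mean = 10)
  expect_equal(d$count, (95 - 100) / 10, tolerance = 1e-12)
  expect_lt(d$count, 0)
  expect_equal(d$density, d$count / 1000, tolerance = 1e-12)
  # calibration-shared rescaling cancels: scale intensities and dot_mean by k
  k <- 7.3
  roi_k <- data.frame(label = "r", integrated_intensity = 95 * k,
                      area_px = 1000)
  d_k <- dots_in_roi(roi_k, background = 0.1 * k, dot_mean = 10 * k)
  expect_equal(d_k$count, d$count, tolerance = 1e-12)
  expect_error(dots_in_roi(roi, 0.1, 0), "dot_mean")
})

test_that("counts are additive over disjoint ROIs", {
  spec <- spot_fixture_spec(seed = 37)
  img <- generate_spot_image(spec)
  led <- img$ledger[img$ledger$region == "calibration", ]
  cal <- data.frame(intensity = led$intensity_raw, area = led$area)
  rois <- spec$roi_polygons
  # split the 'high' region into halves along x = 80
  high_a <- cbind(c(10, 80, 80, 10), c(130, 130, 270, 270))
  high_b <- cbind(c(80, 150, 150, 80), c(130, 130, 270, 270))
  res <- quantify_slices(list(img$image),
                         list(high = rois$high, ha = high_a, hb = high_b),
                         cal, rois$background)
  expect_equal(res$count[res$region == "ha"] + res$count[res$region == "hb"],
               res$count[res$region == "high"], tolerance = 1e-9)
})

test_that("slice quantification is additive and validates regions", {
  spec <- spot_fixture_spec(seed = 41)
  img <- generate_spot_image(spec)
  led <- img$ledger[img$ledger$region == "calibration", ]
  cal <- data.frame(intensity = led$intensity_raw, area = led$area)
  rois <- spec$roi_polygons
  one <- quantify_slices(list(img$image), rois["mid"], cal, rois$background)
  three <- quantify_slices(list(img$image, img$image, img$image), rois["mid"],
                           cal, rois$background)
  expect_equal(three$count, 3 * one$count, tolerance = 1e-9)
  # per-slice results are attached
  expect_equal(nrow(attr(three, "per_slice")$mid), 3)
  # empty region list gives an empty result
  empty <- quantify_slices(list(img$image), list(), cal, rois$background)
  expect_equal(nrow(empty), 0)
  # a region falling outside a slice is an error naming the region
  off <- list(gone = cbind(c(500, 510, 510, 500), c(5, 5, 15, 15)))
  expect_error(quantify_slices(list(img$image), off, cal, rois$background),
               "gone")
})

test_that("planted counts are recovered across regions", {
  counts <- recover_spot_counts(seed = 101)
  expect_lt(abs(counts[["zero"]]), 1)
  expect_lt(abs(counts[["low"]] - 12), max(1, 0.05 * 12))
  expect_lt(abs(counts[["mid"]] - 30), max(1, 0.05 * 30))
  expect_lt(abs(counts[["high"]] - 90), max(1, 0.05 * 90))
})

test_that("counts are invariant when measurement and calibration share a global rescale", {
  spec <- spot_fixture_spec(seed = 53)
  img <- generate_spot_image(spec)
  led <- img$ledger[img$ledger$region == "calibration", ]
  rois <- spec$roi_polygons
  run <- function(image, k) {
    cal <- data.frame(intensity = k * led$intensity_raw, area = led$area)
    quantify_slices(list(image), rois["mid"], cal, rois$background)$count
  }
  expect_equal(run(3 * img$image, 3), run(img$image, 1), tolerance = 1e-9)
})

test_that("candidate-dot helper flags isolated maxima without affecting the statistic", {
  spec <- spot_fixture_spec(seed = 61, noise_sd = 0)
  img <- generate_spot_image(spec)
  cand <- find_candidate_dots(img$image, background = 0.1, min_height = 0.5,
                              min_separation = 6)
  led <- img$ledger
  # every planted dot has a candidate within 1.5 px
  hits <- vapply(seq_len(nrow(led)), function(i) {
    min(sqrt((cand$x - led$x[i])^2 + (cand$y - led$y[i])^2))
  }, numeric(1))
  expect_lt(max(hits), 1.5)
})
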