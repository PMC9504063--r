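test_that("pixel cutoff converts physical area with half-up rounding", {
  expect_identical(px_threshold_from_um2(800, 0.575), 265L)
  expect_identical(px_threshold_from_um2(1, 1), 1L)
  expect_identical(px_threshold_from_um2(1600, 0.575), 529L)
  # scale covariance: doubling the pixel scale quadruples the cutoff (shown
  # where the product is integral; at half-integer products the half-up
  # rounding itself breaks exact quadrupling)
  expect_identical(px_threshold_from_um2(800, 1), 4L * px_threshold_from_um2(800, 0.5))
  expect_identical(px_threshold_from_um2(123, 2), 4L * px_threshold_from_um2(123, 1))
  expect_error(px_threshold_from_um2(-1, 0.575), class = "mgmorph_param_error")
  expect_error(px_threshold_from_um2(800, 0), class = "mgmorph_param_error")
})

test_that("gaussian blur is identity at sigma 0, preserves constants and mass", {
  set.seed(41)
  m <- matrix(runif(30 * 25), 30, 25)
  expect_identical(gaussian_blur(m, 0), m)
  const <- matrix(0.4, 12, 12)
  expect_equal(gaussian_blur(const, 2), const)
  for (s in c(0.25, 1, 2.5)) {
    b <- gaussian_blur(m, s)
    expect_lt(abs(mean(b) - mean(m)) / mean(m), 1e-6)
  }
  expect_error(gaussian_blur(m, -1), class = "mgmorph_param_error")
})

test_that("separable blur matches a dense 2-D kernel convolution oracle", {
  set.seed(42)
  m <- matrix(runif(81), 9, 9)
  for (s in c(0.6, 1)) {
    expect_equal(gaussian_blur(m, s), oracle_gauss_blur(m, s), tolerance = 1e-12)
  }
  # single bright pixel: center equals the discrete kernel's 2-D peak
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  k <- mgmorph:::gaussian_kernel_1d(1)
  expect_equal(gaussian_blur(imp, 1)[6, 6], max(k)^2)
})

test_that("mean threshold is the arithmetic mean with strict binarization", {
  m <- matrix(c(0, 0, 2, 2), 2, 2)
  expect_equal(threshold_value(m, "mean"), 1)
  expect_identical(sum(binarize(m, 1)), 2L)
  # constant image: mean still defined, foreground empty under strict >
  const <- matrix(5, 3, 3)
  expect_equal(threshold_value(const, "mean"), 5)
  expect_false(any(binarize(const, threshold_value(const, "mean"))))
})

test_that("otsu maximizes between-class variance (exhaustive-search oracle)", {
  # discrete gray levels, so the 256-bin histogram is lossless and the
  # implementation must agree exactly with an exhaustive search
  set.seed(7)
  x <- matrix(sample(c(2:6, 30:40) / 50, 480, replace = TRUE,
                     prob = c(rep(3, 5), rep(1, 11))), 24, 20)
  t_pkg <- threshold_value(x, "otsu")
  cands <- sort(unique(as.vector(x)))
  bcv_at <- function(t) {
    lo <- x <= t; w1 <- mean(lo)
    w1 * (1 - w1) * (mean(x[lo]) - mean(x[!lo]))^2
  }
  t_oracle <- cands[which.max(vapply(cands[-length(cands)], bcv_at, numeric(1)))]
  expect_identical(x > t_pkg, x > t_oracle)
  expect_gte(bcv_at(t_pkg), bcv_at(t_oracle) * (1 - 1e-12))
  # cross-check against EBImage: identical binarization
  t_eb <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  expect_identical(x > t_pkg, x > t_eb)
  # two-delta histogram: threshold strictly between the deltas
  td <- matrix(rep(c(0, 10), each = 100), 20, 10)
  t2 <- threshold_value(td, "otsu")
  expect_gt(t2, 0); expect_lt(t2, 10)
})

test_that("histogram methods reject constant images, mean does not", {
  const <- matrix(1, 4, 4)
  for (m in c("isodata", "li", "minimum", "otsu", "triangle", "yen"))
    expect_error(threshold_value(const, m), class = "mgmorph_param_error")
  expect_equal(threshold_value(const, "mean"), 1)
})

test_that("threshold panel covers all seven methods deterministically", {
  set.seed(8)
  img <- matrix(c(rnorm(200, 0.2, 0.02), rnorm(56, 0.8, 0.02)), 16, 16)
  p1 <- threshold_panel(img)
  expect_named(p1, c("isodata", "li", "mean", "minimum", "otsu", "triangle", "yen"))
  expect_length(p1, 7L)
  # two-level image: every method separates the same two populations
  two <- matrix(rep(c(0.2, 0.8), c(200, 56)), 16, 16)
  p2 <- threshold_panel(two)
  ref <- two > 0.5
  for (m in names(p2)) expect_identical(p2[[m]]$mask, ref, label = m)
  # no randomness anywhere
  p3 <- threshold_panel(img)
  expect_identical(vapply(p1, `[[`, numeric(1), "threshold"),
                   vapply(p3, `[[`, numeric(1), "threshold"))
  # degenerate input becomes an annotation, not a failure
  pc <- threshold_panel(matrix(1, 4, 4))
  expect_true(is.na(pc$otsu$threshold))
  expect_match(pc$otsu$error, "constant")
  expect_equal(pc$mean$threshold, 1)
})

test_that("mask cleaning removes small objects, fills holes, clears border", {
  cfg <- seg_config()
  # 100-px blob below the 265-px cutoff vanishes
  m <- matrix(FALSE, 60, 60); m[20:29, 20:29] <- TRUE
  expect_identical(n_cells(clean_mask(m, cfg, 0.575)), 0L)
  # ring away from the border: hole filled, solidity increases
  ring <- matrix(FALSE, 80, 80)
  ring[20:59, 20:59] <- TRUE; ring[28:51, 28:51] <- FALSE  # 1024-px ring
  cleaned <- clean_mask(ring, cfg, 0.575)
  expect_identical(n_cells(cleaned), 1L)
  sol_ring <- sum(ring) / (40 * 40)
  cells <- measure_cells(cleaned)
  expect_gt(cells$solidity, sol_ring)
  expect_identical(cells$area_px, 1600L)
  # blob touching row 1 is removed even though it is large
  b <- matrix(FALSE, 60, 60); b[1:20, 10:40] <- TRUE
  expect_identical(n_cells(clean_mask(b, cfg, 0.575)), 0L)
  # empty mask allowed
  expect_identical(n_cells(clean_mask(matrix(FALSE, 10, 10), cfg, 0.575)), 0L)
})

test_that("cleaning order is size filter, then fill, then border clear", {
  cfg <- seg_config()
  # a sub-threshold ring whose hole-fill would exceed the cutoff: filtering
  # before filling must remove it; fill-first would keep it.
  # width-2 frame of outer side 34: area 34^2 - 30^2 = 256 px < 265
  f <- matrix(FALSE, 60, 60); f[10:43, 10:43] <- TRUE; f[12:41, 12:41] <- FALSE
  expect_identical(sum(f), 256L)  # sub-threshold ring
  expect_identical(n_cells(clean_mask(f, cfg, 0.575)), 0L)
  # whereas its filled version (34^2 = 1156 px) would survive
  filled <- matrix(FALSE, 60, 60); filled[10:43, 10:43] <- TRUE
  expect_identical(n_cells(clean_mask(filled, cfg, 0.575)), 1L)
})

test_that("labeling respects the configured connectivity", {
  m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(mgmorph:::label_components(m, 8L)), 1L)
  expect_identical(max(mgmorph:::label_components(m, 4L)), 2L)
  # raster-scan (reading order) relabeling
  two <- matrix(FALSE, 10, 10); two[6:8, 2:4] <- TRUE; two[2:4, 6:8] <- TRUE
  lab <- mgmorph:::label_components(two, 8L)
  expect_identical(lab[2, 6], 1L)  # upper-right blob read first
  expect_identical(lab[6, 2], 2L)
})

test_that("full segmentation recovers noiseless planted cells exactly", {
  spec <- cohort_spec(groups = list(
    g = list(n_images = 1, cells_per_image_mean = 10,
             shape_mixture = c(amoeboid = 0.6, ramified = 0.4))),
    noise_sd = 0, seed = 77)
  gi <- generate_image(spec, "g", 1)
  mask <- segment(gi$image)
  expect_identical(n_cells(mask), gi$truth$n_cells)
  prov <- mask$provenance
  expect_equal(prov$blur_sigma, 0.25)
  expect_identical(prov$threshold_method, "mean")
  expect_identical(prov$min_area_px, 265L)
  expect_true(prov$border_cleared)
  # empty image segments to zero labels
  empty <- micrograph(matrix(0.1, 64, 64), 0.575)
  expect_identical(n_cells(segment(empty)), 0L)
})

test_that("a 700 um^2 cell falls below the default cutoff and is dropped", {
  # 700 * 0.575^2 = 231 px < 265
  r_um <- sqrt(700 / pi)
  stamp <- render_cell(shape_class_spec(r_um), px_per_um = 0.575, rng_seed = 3)
  expect_lt(sum(stamp), 265)
  img <- matrix(0, 128, 128)
  img[40 + seq_len(nrow(stamp)), 40 + seq_len(ncol(stamp))][stamp] <- 0.8
  mask <- segment(micrograph(img, 0.575))
  expect_identical(n_cells(mask), 0L)
})
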