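# Image-based gradient profiling.

test_that("ROI binning averages pixels with the documented geometry", {
  # constant image: every bin equals the constant
  img <- embryo_image(matrix(7, 64, 100), source_boundary = 1)
  pr <- extract_binned_profile(img)
  expect_true(all(abs(pr$intensity - 7) < 1e-12))
  # 5 px bins at 1.4 um/px: first centre at 3.5 um, pitch 7 um;
  # 36 px ROI is 50.4 um tall
  expect_equal(pr$distance[1], 3.5, tolerance = 1e-12)
  expect_equal(diff(pr$distance)[1], 7, tolerance = 1e-12)
  expect_equal(36 * 1.4, 50.4, tolerance = 1e-12)
  # exponential image: bins equal the direct pixel-block means
  lam <- 25
  cols <- 0:99 * 1.4
  m <- matrix(exp(-cols / lam), 64, 100, byrow = TRUE)
  img2 <- embryo_image(m, source_boundary = 1)
  pr2 <- extract_binned_profile(img2)
  oracle <- vapply(seq_len(20), function(b)
    mean(exp(-cols[(5 * b - 4):(5 * b)] / lam)), numeric(1))
  expect_equal(pr2$intensity, oracle, tolerance = 1e-12)
  # and they track the analytic bin-averaged exponential closely
  cont <- vapply(seq_len(20), function(b)
    oracle_bin_averaged_exp(lam, (b - 1) * 7 - 0.7, b * 7 - 0.7),
    numeric(1))
  expect_equal(pr2$intensity, cont, tolerance = 1e-3)
  # ROI geometry errors
  expect_error(extract_binned_profile(img, roi_height_px = 100), "ROI")
  expect_error(extract_binned_profile(
    embryo_image(matrix(1, 64, 3), source_boundary = 1)), "ROI")
})

test_that("profile extraction is linear in the image intensities", {
  set.seed(10)
  m <- matrix(stats::runif(64 * 80, 1, 5), 64, 80)
  a <- 2.5; b <- 3
  pr1 <- extract_binned_profile(embryo_image(m))
  pr2 <- extract_binned_profile(embryo_image(a * m + b))
  expect_equal(pr2$intensity, a * pr1$intensity + b, tolerance = 1e-9)
})

test_that("background subtraction clips at zero and normalisation pins the first bin", {
  pr <- intensity_profile(c(3.5, 10.5, 17.5), c(10, 6, 2))
  expect_equal(subtract_background(pr, 0)$intensity, pr$intensity)
  expect_equal(subtract_background(pr, 10)$intensity, c(0, 0, 0))
  sub <- subtract_background(pr, 4)
  expect_equal(sub$intensity, c(6, 2, 0))
  nrm <- normalize_profile(sub)
  expect_equal(nrm$intensity[1], 1)
  # scale invariance of normalisation
  nrm2 <- normalize_profile(intensity_profile(pr$distance,
                                              5 * sub$intensity))
  expect_equal(nrm2$intensity, nrm$intensity, tolerance = 1e-12)
  expect_error(normalize_profile(intensity_profile(pr$distance,
                                                   c(0, 1, 2))),
               "not positive")
})

test_that("gradient fits recover the decay length exactly on clean profiles", {
  x <- seq(3.5, 350, by = 7)
  fit <- fit_profile(intensity_profile(x, exp(-x / 29.5)))
  expect_equal(fit$lambda_, 29.5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-6)
  # invariance to intensity scaling and additive background
  fit2 <- fit_profile(intensity_profile(x, 840 * exp(-x / 29.5) + 12))
  expect_equal(fit2$lambda_, 29.5, tolerance = 1e-6)
  expect_equal(fit2$amplitude, 840, tolerance = 1e-4)
  expect_equal(fit2$offset, 12, tolerance = 1e-4)
})

test_that("pooled and individual aggregation agree and average correctly", {
  x <- seq(3.5, 350, by = 7)
  p20 <- intensity_profile(x, exp(-x / 20))
  p40 <- intensity_profile(x, exp(-x / 40))
  # identical profiles: both modes give the same length
  same_pool <- aggregate_profiles(list(p20, p20), mode = "pooled")
  same_ind <- aggregate_profiles(list(p20, p20), mode = "individual")
  expect_equal(same_pool$lambda_, 20, tolerance = 1e-6)
  expect_equal(same_ind$lambda_, 20, tolerance = 1e-6)
  # individual mode averages the per-embryo lengths
  ind <- aggregate_profiles(list(p20, p40), mode = "individual")
  expect_equal(ind$lambda_, 30, tolerance = 1e-6)
  # incompatible grids are rejected
  p_bad <- intensity_profile(x + 1, exp(-x / 20))
  expect_error(aggregate_profiles(list(p20, p_bad)), "incompatible")
  # noisy synthetic set: the two procedures give similar lengths
  profs <- lapply(1:6, function(s) {
    img <- synth_gradient_image(19.7, noise_level = 0.05, seed = 100 + s,
                               shape_px = c(128, 256))
    normalize_profile(subtract_background(extract_binned_profile(img),
                                          img$background_level))
  })
  pool <- aggregate_profiles(profs, mode = "pooled")
  ind2 <- aggregate_profiles(profs, mode = "individual")
  expect_lt(abs(pool$lambda_ - ind2$lambda_) / ind2$lambda_, 0.10)
})

test_that("decay lengths are recovered from synthetic embryo images", {
  # clean image: near-exact recovery through the full pipeline
  img0 <- synth_gradient_image(29.5, noise_level = 0, seed = 1,
                               shape_px = c(128, 256))
  pr0 <- normalize_profile(subtract_background(
    extract_binned_profile(img0), img0$background_level))
  expect_lt(abs(fit_profile(pr0)$lambda_ - 29.5) / 29.5, 0.01)
  # SNR 10: recovery within 10%
  img <- synth_gradient_image(29.5, noise_level = 0.1, seed = 4)
  pr <- normalize_profile(subtract_background(
    extract_binned_profile(img), img$background_level))
  expect_lt(abs(fit_profile(pr)$lambda_ - 29.5) / 29.5, 0.10)
})

test_that("embryo images survive a 16-bit TIFF round trip", {
  img <- synth_gradient_image(25, amplitude = 40000, background = 2000,
                              noise_level = 0.02, seed = 2,
                              shape_px = c(64, 128))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pmin(img$pixels / 65535, 1), path,
                  bits.per.sample = 16L)
  back <- read_embryo_tiff(path, source_boundary = img$source_boundary,
                           background_level = img$background_level)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_lt(max(abs(back$pixels - img$pixels)), 1) # quantisation only
  pr <- normalize_profile(subtract_background(
    extract_binned_profile(back), back$background_level))
  expect_lt(abs(fit_profile(pr)$lambda_ - 25) / 25, 0.05)
})
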