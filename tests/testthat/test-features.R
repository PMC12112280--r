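# Morphometry features: contrast, noise sigma, skeleton, density,
# heterogeneity and its detrend.

test_that("contrast is the vessel/background mean ratio with its invariances", {
  img <- matrix(50, 4, 4)
  msk <- matrix(0L, 4, 4)
  msk[1, 1:4] <- 1L
  img[1, 1:2] <- 200
  img[1, 3:4] <- 100
  expect_equal(compute_contrast(img, msk), 3.0) # 150 / 50

  const <- matrix(100, 4, 4)
  expect_equal(compute_contrast(const, msk), 1.0)

  # invariant to positive intensity scaling
  expect_equal(compute_contrast(7.3 * img, msk), 3.0)

  expect_error(compute_contrast(img, matrix(0L, 4, 4)), "no vessel")
  expect_error(compute_contrast(img, matrix(1L, 4, 4)), "no background")
  zero_bg <- img
  zero_bg[msk == 0] <- 0
  expect_error(compute_contrast(zero_bg, msk), "zero")
})

test_that("wavelet noise sigma recovers known Gaussian noise and ignores vessels", {
  const <- matrix(100, 64, 64)
  expect_equal(estimate_noise_sigma(const), 0)

  set.seed(101)
  noise <- matrix(rnorm(256 * 256, sd = 10), 256, 256)
  img <- 100 + noise
  est <- estimate_noise_sigma(img)
  expect_gt(est, 9)
  expect_lt(est, 11)

  # a thick masked-out vessel must not inflate the estimate
  vessel_mask <- matrix(0L, 256, 256)
  vessel_mask[100:140, ] <- 1L
  img2 <- img
  img2[vessel_mask == 1L] <- img2[vessel_mask == 1L] + 150
  est2 <- estimate_noise_sigma(img2, vessel_mask)
  expect_gt(est2, 9)
  expect_lt(est2, 11)

  # masking almost everything leaves too few coefficients
  tiny_bg <- matrix(1L, 64, 64)
  tiny_bg[1:4, 1:4] <- 0L
  expect_error(estimate_noise_sigma(img[1:64, 1:64], tiny_bg), "Fewer than 16")
})

test_that("noise estimator accuracy: <10% mean relative error across sigma levels", {
  for (sigma in c(5, 10, 20)) {
    rel_err <- vapply(1:20, function(s) {
      set.seed(s)
      img <- 100 + matrix(rnorm(256 * 256, sd = sigma), 256, 256)
      abs(estimate_noise_sigma(img) - sigma) / sigma
    }, numeric(1))
    expect_lt(mean(rel_err), 0.10)
  }
})

test_that("skeletonization thins bars to single runs, preserves components, is idempotent", {
  expect_equal(sum(skeletonize_mask(matrix(0L, 10, 10))), 0)

  bar <- matrix(0L, 30, 120)
  bar[10:14, 5:104] <- 1L
  sk <- skeletonize_mask(bar)
  expect_true(all(bar[sk == 1] == 1)) # subset of foreground
  expect_equal(sum(rowSums(sk) > 0), 1) # a single 1-px horizontal run
  expect_equal(oracle_n_components(sk), 1)
  expect_identical(skeletonize_mask(sk), sk) # idempotent on 1-px lines

  tubes <- fixture_two_tubes()
  sk2 <- skeletonize_mask(tubes)
  expect_equal(oracle_n_components(sk2), oracle_n_components(tubes))
})

test_that("density follows the 1 / sqrt(2) step-count convention", {
  expect_equal(compute_density(matrix(0L, 16, 16)), 0)

  horiz <- matrix(0L, 256, 256)
  horiz[10, 1:100] <- 1L
  expect_equal(compute_density(horiz), 99 / 65536)

  diag <- matrix(0L, 256, 256)
  diag[cbind(1:100, 1:100)] <- 1L
  expect_equal(compute_density(diag), 99 * sqrt(2) / 65536)

  # brute-force oracle equivalence on random small masks
  set.seed(7)
  for (i in 1:100) {
    m <- matrix(rbinom(100, 1, 0.3), 10, 10)
    expect_equal(skeleton_length(m), oracle_arc_length(m))
  }
})

test_that("medial heterogeneity is the population sd of blurred skeleton samples", {
  const <- matrix(42, 32, 32)
  sk <- matrix(0L, 32, 32)
  sk[16, 5:25] <- 1L
  het <- compute_medial_heterogeneity(const, sk)
  expect_equal(het$h, 0)
  expect_equal(het$m, 42)

  # shift invariance of h, equivariance of m
  img <- matrix(runif(32 * 32) * 100, 32, 32)
  h0 <- compute_medial_heterogeneity(img, sk)
  h1 <- compute_medial_heterogeneity(img + 13.5, sk)
  expect_equal(h1$h, h0$h)
  expect_equal(h1$m, h0$m + 13.5)

  expect_error(compute_medial_heterogeneity(img, matrix(0L, 32, 32)), "at least 2")
})

test_that("population sd convention on known values", {
  # values {10, 10, 20, 20} -> h = 5, m = 15 (verified by direct computation)
  vals <- c(10, 10, 20, 20)
  expect_equal(sqrt(mean((vals - mean(vals))^2)), 5)
  # the same arithmetic through the feature path: delta pixels away from any
  # blur interaction are not practical on a tiny fixture, so assert the
  # convention via the exported detrend/feature outputs instead.
  sk <- matrix(0L, 8, 8)
  sk[2, 2:5] <- 1L
  img <- matrix(0, 8, 8)
  # constant columns so the unit blur leaves row-wise values unchanged
  img[, 2] <- 10; img[, 3] <- 10; img[, 4] <- 20; img[, 5] <- 20
  img[, 6] <- 20; img[, 1] <- 10
  het <- compute_medial_heterogeneity(img, sk)
  expect_equal(het$m, mean(gaussian_blur(img)[sk == 1]))
  expect_equal(het$h, sqrt(mean((gaussian_blur(img)[sk == 1] - het$m)^2)))
})

test_that("heterogeneity detrend is OLS with zero-sum residuals", {
  # exact linear relation is removed completely
  m <- c(10, 20, 30, 40)
  h <- 2 * m + 1
  dt <- detrend_heterogeneity(data.frame(h = h, m = m))
  expect_equal(dt$fit$slope, 2)
  expect_equal(dt$fit$intercept, 1)
  expect_equal(dt$het_detrended, rep(0, 4))
  expect_false(dt$fit$degenerate)

  # two-point line
  dt2 <- detrend_heterogeneity(data.frame(h = c(0, 5), m = c(0, 10)))
  expect_equal(dt2$fit$slope, 0.5)
  expect_equal(dt2$fit$intercept, 0)
  expect_equal(dt2$het_detrended, c(0, 0))

  # generic collections: residuals sum to 0; refit recovers the line
  set.seed(3)
  for (i in 1:10) {
    mm <- runif(30, 50, 200)
    hh <- 0.1 * mm + rnorm(30)
    dt3 <- detrend_heterogeneity(data.frame(h = hh, m = mm))
    expect_equal(sum(dt3$het_detrended), 0, tolerance = 1e-9)
    recon <- dt3$het_detrended + dt3$fit$slope * mm + dt3$fit$intercept
    dt4 <- detrend_heterogeneity(data.frame(h = recon, m = mm))
    expect_equal(dt4$fit$slope, dt3$fit$slope, tolerance = 1e-9)
    expect_equal(dt4$fit$intercept, dt3$fit$intercept, tolerance = 1e-9)
  }

  # degenerate: all m identical
  dt5 <- detrend_heterogeneity(data.frame(h = c(1, 3), m = c(5, 5)))
  expect_true(dt5$fit$degenerate)
  expect_equal(dt5$fit$slope, 0)
  expect_equal(dt5$fit$intercept, 2)
})

test_that("collection features assemble in fixed column order with detrended h", {
  coll <- generate_collection(6, image_size = c(64, 64), seed = 31)
  feats <- compute_collection_features(coll)
  expect_s3_class(feats, "mapped_dataset")
  expect_identical(feature_cols(feats),
                   c("contrast", "noise", "density", "het_detrended"))
  expect_equal(nrow(feats), 6)
  expect_equal(sum(feats$het_detrended), 0, tolerance = 1e-9)

  # single sample: degenerate detrend forces h_detrended = 0
  one <- compute_collection_features(coll[1, ])
  expect_equal(one$het_detrended, 0)

  # two noiseless contrast levels separate exactly
  pinned <- list(noise_sigma = c(0, 0), heterogeneity_amplitude = c(0, 0),
                 background_mean_intensity = c(50, 50))
  lo <- generate_collection(3, c(pinned, list(vessel_mean_intensity = c(100, 100))),
                            image_size = c(64, 64), seed = 8)
  hi <- generate_collection(3, c(pinned, list(vessel_mean_intensity = c(200, 200))),
                            image_size = c(64, 64), seed = 9)
  both <- dplyr::bind_rows(lo, hi)
  both$sample_id <- sprintf("s%d", 1:6)
  f <- compute_collection_features(both)
  expect_true(max(f$contrast[1:3]) < min(f$contrast[4:6]))
  expect_equal(f$contrast, c(rep(2, 3), rep(4, 3)))
})
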