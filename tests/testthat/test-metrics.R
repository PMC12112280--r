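# Dice, clDice, EWMA smoothing, loss-gap delta, score summaries.

test_that("dice: overlap ratio with defined degenerate cases", {
  a <- matrix(0L, 8, 8)
  a[2:3, 2:3] <- 1L # |A| = 4
  b <- matrix(0L, 8, 8)
  b[2:3, 3:4] <- 1L # |B| = 4, |A n B| = 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(b, a), dice(a, b))

  disjoint <- matrix(0L, 8, 8)
  disjoint[6:7, 6:7] <- 1L
  expect_equal(dice(a, disjoint), 0)

  empty <- matrix(0L, 8, 8)
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(a, empty), 0)
  expect_error(dice(a, matrix(0L, 4, 4)), "identical dimensions")
})

test_that("clDice: identical masks 1, disjoint 0, symmetric, in [0,1]", {
  tube <- matrix(0L, 40, 80)
  tube[18:22, 10:70] <- 1L
  expect_equal(cl_dice(tube, tube), 1)

  other <- matrix(0L, 40, 80)
  other[30:34, 10:70] <- 1L
  expect_equal(cl_dice(tube, other), 0)

  empty <- matrix(0L, 40, 80)
  expect_equal(cl_dice(empty, empty), 1)
  expect_equal(cl_dice(tube, empty), 0)
  expect_equal(cl_dice(empty, tube), 0)

  set.seed(4)
  for (i in 1:5) {
    p <- generate_vessel_image(vessel_params(image_size = c(64, 64), seed = i))
    q <- generate_vessel_image(vessel_params(image_size = c(64, 64), seed = i + 100))
    v <- cl_dice(p$mask, q$mask)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(cl_dice(q$mask, p$mask), v)
  }
})

test_that("clDice equals 2/3 when half the prediction skeleton leaves the reference", {
  # Construct pred as a long bar; cut the reference so exactly half of the
  # prediction's skeleton pixels fall inside it. Since gt is a subset of pred,
  # the gt skeleton lies inside pred and topology sensitivity is 1; topology
  # precision is forced to 1/2 by the cut, so clDice = 2 * 0.5 / 1.5 = 2/3.
  pred <- matrix(0L, 30, 212)
  pred[13:17, 5:205] <- 1L
  sk <- skeletonize_mask(pred)
  px <- which(sk == 1L, arr.ind = TRUE)
  expect_equal(nrow(px), 196) # single even-length run for an exact halving
  cut_col <- sort(px[, 2])[nrow(px) / 2]
  gt <- pred
  gt[, (cut_col + 1):ncol(gt)] <- 0L

  # forced counts, verified by explicit enumeration on the fixture
  expect_equal(sum(sk & gt) / sum(sk), 0.5)
  sk_gt <- skeletonize_mask(gt)
  expect_equal(sum(sk_gt & pred) / sum(sk_gt), 1)
  expect_equal(cl_dice(pred, gt), 2 / 3)
})

test_that("ewma follows the recursive definition with its equivariances", {
  expect_equal(ewma(c(0, 1), 0.9), c(0, 0.1))
  expect_equal(ewma(rep(3.5, 10), 0.8), rep(3.5, 10)) # constant fixed point
  # alpha -> 0 limit approaches the identity
  x <- c(1, 4, 2, 8)
  expect_equal(ewma(x, 1e-9), x, tolerance = 1e-6)
  expect_error(ewma(x, 0), "inside")
  expect_error(ewma(x, 1), "inside")

  set.seed(1)
  y <- rnorm(50)
  expect_equal(ewma(y + 2.5, 0.7), ewma(y, 0.7) + 2.5)
  expect_equal(ewma(3 * y, 0.7), 3 * ewma(y, 0.7))
  # explicit recursion oracle
  s <- numeric(50)
  s[1] <- y[1]
  for (t in 2:50) s[t] <- 0.7 * s[t - 1] + 0.3 * y[t]
  expect_equal(ewma(y, 0.7), s)
})

test_that("delta gap is the smoothed train-minus-val readout, antisymmetric", {
  same <- loss_curves(rep(0.3, 200), rep(0.3, 200))
  expect_equal(delta_gap(same), 0)

  set.seed(9)
  tr <- 0.5 * exp(-(1:200) / 60) + rnorm(200, sd = 0.01)
  vl <- 0.6 * exp(-(1:200) / 90) + rnorm(200, sd = 0.01)
  d <- delta_gap(loss_curves(tr, vl))
  d_swap <- delta_gap(loss_curves(vl, tr))
  expect_equal(d, -d_swap)
  st <- ewma(tr, 0.9)
  sv <- ewma(vl, 0.9)
  expect_equal(d, st[150] - sv[150])

  expect_error(loss_curves(tr, vl[-1]), "same length")
  expect_error(loss_curves(tr[1:100], vl[1:100], eval_epoch = 150), "within")
})

test_that("score summaries compute quartiles, whiskers and mean range", {
  scores <- data.frame(
    sample_id = rep(c("a", "b"), each = 5),
    score = c(1, 2, 3, 4, 5, rep(0.5, 5))
  )
  sm <- score_distribution_summary(scores)
  td <- tidy(sm)
  # order-statistic oracle on 1..5 (type-7 linear interpolation)
  expect_equal(td$q1[td$sample_id == "a"], 2)
  expect_equal(td$median[td$sample_id == "a"], 3)
  expect_equal(td$q3[td$sample_id == "a"], 4)
  expect_equal(td$whisker_low[td$sample_id == "a"], 2 - 1.5 * 2)
  expect_equal(td$whisker_high[td$sample_id == "a"], 4 + 1.5 * 2)
  expect_equal(td$range[td$sample_id == "a"], 4)
  expect_equal(td$range[td$sample_id == "b"], 0)
  g <- glance(sm)
  expect_equal(g$mean_range, 2)

  # single score per sample: zero ranges
  single <- data.frame(sample_id = c("a", "b"), score = c(0.2, 0.8))
  expect_equal(glance(score_distribution_summary(single))$mean_range, 0)
  # two-point range
  two <- data.frame(sample_id = "a", score = c(0.2, 0.8))
  expect_equal(tidy(score_distribution_summary(two))$range, 0.6)

  expect_error(score_distribution_summary(data.frame()), "columns")
})
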