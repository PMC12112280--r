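# Normalization, grid discretization, hypersphere sampling set, FUS and
# subset selection.

make_md <- function(coords, source_ids = NULL, normalized = TRUE) {
  n <- nrow(coords)
  if (is.null(source_ids)) source_ids <- sprintf("src%04d", seq_len(n))
  tbl <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    source_id = source_ids
  )
  for (j in seq_len(ncol(coords))) tbl[[paste0("f", j)]] <- coords[, j]
  vesselect::new_mapped_dataset(tbl, paste0("f", seq_len(ncol(coords))),
                                normalized = normalized)
}

make_grid <- function(coords, source_ids = NULL) {
  md <- make_md(coords, source_ids)
  discretize_features(md, cell_width = 1)
}

test_that("normalization z-scores columns and stores reusable statistics", {
  md <- make_md(cbind(c(1, 2, 3), c(10, 20, 60)), normalized = FALSE)
  nz <- normalize_features(md)
  m <- feature_matrix(nz)
  expect_equal(unname(m[, 1]), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_equal(unname(colMeans(m)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(m, 2, function(x) mean((x - mean(x))^2))), c(1, 1),
               tolerance = 1e-9)

  # round trip with the stored statistics
  raw <- feature_matrix(md)
  mu <- attr(nz, "norm_means")
  sdv <- attr(nz, "norm_stds")
  expect_equal(sweep(sweep(raw, 2, mu), 2, sdv, "/"), m, tolerance = 1e-12)

  # idempotent within tolerance
  nz2 <- normalize_features(nz)
  expect_equal(feature_matrix(nz2), feature_matrix(nz), tolerance = 1e-9)

  const <- make_md(cbind(c(1, 1, 1), c(1, 2, 3)), normalized = FALSE)
  expect_error(normalize_features(const), "f1")
})

test_that("discretization floors values against the realized cell width", {
  md <- make_md(cbind(c(0.37, -0.1, 0.0, 0.26)))
  g <- discretize_features(md, cell_width = 0.25)
  expect_equal(g$coords[, 1], c(1L, -1L, 0L, 1L)) # floor, not truncation
  expect_equal(g$cell_width, 0.25)

  # nu sets the number of cells across the observed range
  md2 <- make_md(cbind(seq(0, 1, length.out = 11)))
  g2 <- discretize_features(md2, nu = 10)
  expect_equal(g2$cell_width, 0.1)
  expect_equal(max(g2$coords) - min(g2$coords), 10L)

  # all points in one cell collapse to identical coordinates
  md3 <- make_md(cbind(c(0.01, 0.02, 0.03), c(0.01, 0.02, 0.03)))
  g3 <- discretize_features(md3, cell_width = 1)
  expect_true(all(g3$coords == 0L))

  expect_error(discretize_features(md, nu = -1), "positive")
  raw <- make_md(cbind(1:3), normalized = FALSE)
  expect_error(discretize_features(raw), "normalized")
})

test_that("ball offsets match exhaustive enumeration for d in 1..4, r in 0..4", {
  expect_equal(ball_offsets(2, 0), matrix(0L, 1, 2), ignore_attr = TRUE)
  expect_equal(nrow(ball_offsets(2, 1)), 5)
  expect_equal(nrow(ball_offsets(4, 1)), 9)
  for (d in 1:4) {
    for (r in 0:4) {
      expect_identical(unname(ball_offsets(d, r)), unname(oracle_ball(d, r)),
                       label = sprintf("d=%d r=%d", d, r))
    }
  }
})

test_that("the sampling set is the union of balls over occupied cells", {
  g1 <- make_grid(cbind(0L, 0L))
  expect_equal(build_sampling_set(g1, 0)$points, g1$coords[1, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(nrow(build_sampling_set(g1, 1)$points), 5)

  # same-cell duplicates do not enlarge the set
  g2 <- make_grid(rbind(c(0L, 0L), c(0L, 0L)))
  expect_identical(build_sampling_set(g2, 1)$points,
                   build_sampling_set(g1, 1)$points)

  # r = 0 returns exactly the occupied cells
  set.seed(5)
  coords <- matrix(sample(-3:3, 40, replace = TRUE), 20, 2)
  g3 <- make_grid(coords)
  s0 <- build_sampling_set(g3, 0)
  expected <- unique(coords)
  expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
  storage.mode(expected) <- "integer"
  expect_equal(unname(s0$points), unname(expected))
  # every data cell is inside any sampling set
  s2 <- build_sampling_set(g3, 2)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_true(all(key(coords) %in% key(s2$points)))
})

test_that("FUS equals the brute-force oracle and honors edge cases", {
  # 1-D line 0..9 with ends selected: farthest unselected is 4 away
  g <- make_grid(cbind(0:9))
  expect_equal(fus_metric(c(1, 10), g), 4)
  expect_equal(fus_metric(1:10, g), 0)
  expect_error(fus_metric(integer(0), g), "non-empty")

  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    d <- sample(1:4, 1)
    coords <- matrix(sample(-10:10, n * d, replace = TRUE), n, d)
    gg <- make_grid(coords)
    k <- sample(1:(n - 1), 1)
    sel <- sample(n, k)
    expect_equal(fus_metric(sel, gg), oracle_fus(sel, coords))
  }
})

test_that("draw_subset selects k distinct samples, excludes same sources, is seeded", {
  set.seed(21)
  coords <- matrix(sample(-5:5, 60, replace = TRUE), 30, 2)
  g <- make_grid(coords)
  ss <- build_sampling_set(g, 1)
  res <- draw_subset(ss, g, k = 10, seed = 3)
  expect_length(unique(res$selected_indices), 10)
  expect_length(unique(res$source_ids), 10)
  expect_equal(res$fus, fus_metric(res$selected_indices, g))

  res2 <- draw_subset(ss, g, k = 10, seed = 3)
  expect_identical(res$selected_indices, res2$selected_indices)

  # forced selection: k = n, distinct sources, sset = data coords
  uniq <- unique_coords <- unique(coords)
  gu <- make_grid(uniq)
  su <- build_sampling_set(gu, 0)
  all_sel <- draw_subset(su, gu, k = nrow(uniq), seed = 99)
  expect_setequal(all_sel$selected_indices, seq_len(nrow(uniq)))
  expect_equal(all_sel$fus, 0)

  # one shared source makes k = 2 infeasible before drawing
  g_same <- make_grid(coords[1:10, ], source_ids = rep("one", 10))
  ss_same <- build_sampling_set(g_same, 1)
  expect_error(draw_subset(ss_same, g_same, k = 2, seed = 1), "distinct sources")
})

test_that("select_best_subset minimizes FUS over replayable derived trials", {
  set.seed(31)
  coords <- matrix(sample(-6:6, 80, replace = TRUE), 40, 2)
  g <- make_grid(coords)
  ss <- build_sampling_set(g, 1)

  best <- select_best_subset(ss, g, k = 8, n_trials = 25, seed = 7)
  expect_equal(best$fus, min(best$trial_fus))
  expect_equal(best$trial_seeds, 7 + 1:25)
  # replay the winning trial
  replay <- draw_subset(ss, g, k = 8, seed = best$seed)
  expect_identical(replay$selected_indices, best$selected_indices)
  expect_equal(replay$fus, best$fus)
  # n_trials = 1 reduces to draw_subset with the derived seed
  one <- select_best_subset(ss, g, k = 8, n_trials = 1, seed = 7)
  expect_identical(one$selected_indices,
                   draw_subset(ss, g, k = 8, seed = 8)$selected_indices)

  # nested trials: FUS non-increasing in n_trials
  fus_by_trials <- vapply(c(5, 10, 25), function(tr) {
    select_best_subset(ss, g, k = 8, n_trials = tr, seed = 7)$fus
  }, numeric(1))
  expect_true(all(diff(fus_by_trials) <= 0))
})

test_that("FUS-minimized selection over-represents a rare cluster", {
  cloud <- generate_feature_cloud(800, c(0.95, 0.05),
                                  list(rep(0, 4), rep(8, 4)), seed = 5)
  nz <- normalize_features(cloud)
  g <- discretize_features(nz, nu = 10)
  ss <- build_sampling_set(g, r = 4)
  sel <- select_best_subset(ss, g, k = 20, n_trials = 50, seed = 13)
  minority <- sum(cloud$cluster[sel$selected_indices] == 2)
  # frequency-proportional sampling would pick 1 of 20 on average
  expect_gte(minority, 3)
})

test_that("monotone coverage: best-subset FUS non-increasing in k", {
  set.seed(41)
  coords <- matrix(sample(-6:6, 100, replace = TRUE), 50, 2)
  g <- make_grid(coords)
  ss <- build_sampling_set(g, 1)
  for (seed in 1:5) {
    fus_k <- vapply(c(5, 10, 20), function(k) {
      select_best_subset(ss, g, k = k, n_trials = 20, seed = seed)$fus
    }, numeric(1))
    expect_true(all(diff(fus_k) <= 1e-12))
  }
})
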