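# Distribution-shift train/validation split generation.

new_split_spec <- function(train, val, provenance) {
  structure(
    list(
      train_indices = as.integer(train),
      val_indices = as.integer(val),
      provenance = provenance
    ),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> train n = %d, val n = %d, type = %s\n",
    length(x$train_indices), length(x$val_indices), x$provenance$type
  ))
  invisible(x)
}

#' @describeIn extreme_feature_split Tidy a split into a long tibble
#'   (columns `set` and `index`).
#' @method tidy split_spec
#' @param x A `split_spec`.
#' @param ... Unused.
#' @export
tidy.split_spec <- function(x, ...) {
  tibble(
    set = rep(c("train", "val"),
              c(length(x$train_indices), length(x$val_indices))),
    index = c(x$train_indices, x$val_indices)
  )
}

#' Split by feature extremes
#'
#' Sorts the samples by one feature and puts the `n` most extreme samples on
#' one side into the training set and the `n` most extreme on the opposite
#' side into the validation set. Training on one tail and validating on the
#' other creates a controlled distribution shift along that feature. Ties are
#' broken by sample index (stable sort), and swapping `train_side` exactly
#' swaps the two sets.
#'
#' @param features A [new_mapped_dataset()].
#' @param feature Feature column name or index among `feature_cols(features)`.
#' @param n Samples per side (`2 * n` must not exceed the dataset size).
#' @param train_side `"low"` to train on the smallest values, `"high"` for the
#'   largest.
#' @return A `split_spec` with provenance
#'   `feature_extreme(feature, direction, n)`.
#' @export
extreme_feature_split <- function(features, feature, n = 20L,
                                  train_side = c("low", "high")) {
  stopifnot(inherits(features, "mapped_dataset"))
  train_side <- match.arg(train_side)
  if (!is_count(n, min = 1L)) abort("`n` must be a positive integer.")
  if (2L * n > nrow(features)) {
    abort(sprintf("2 * n = %d exceeds the dataset size (%d).", 2L * n, nrow(features)))
  }
  fc <- feature_cols(features)
  fname <- if (is.numeric(feature)) fc[feature] else feature
  if (is.na(fname) || !(fname %in% fc)) {
    abort(sprintf("Unknown feature `%s`; available: %s.",
                  as.character(feature), paste(fc, collapse = ", ")))
  }
  ord <- order(features[[fname]], seq_len(nrow(features)))
  low <- ord[seq_len(n)]
  high <- ord[seq(length(ord) - n + 1L, length(ord))]
  train <- if (train_side == "low") low else high
  val <- if (train_side == "low") high else low
  new_split_spec(train, val, list(
    type = "feature_extreme", feature = fname, direction = train_side, n = n
  ))
}

#' Minimum cross-set distance
#'
#' The smallest Euclidean distance between any point of `set_a` and any point
#' of `set_b`. Distances are meaningful on z-scored features, so pass rows of
#' a normalized feature matrix.
#'
#' @param set_a,set_b Numeric matrices (rows = points) with equal column
#'   counts; both non-empty.
#' @return The minimum pairwise distance (>= 0); symmetric in its arguments.
#' @export
min_cross_distance <- function(set_a, set_b) {
  set_a <- as.matrix(set_a)
  set_b <- as.matrix(set_b)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) abort("Both sets must be non-empty.")
  if (ncol(set_a) != ncol(set_b)) abort("Sets must have the same dimension.")
  d2 <- outer(rowSums(set_a^2), rep(1, nrow(set_b))) +
    outer(rep(1, nrow(set_a)), rowSums(set_b^2)) -
    2 * set_a %*% t(set_b)
  sqrt(max(0, min(d2)))
}

#' Find a far-apart split
#'
#' Draws `n_candidates` random splits of `n` training and `n` validation
#' samples (disjoint, drawn without replacement), scores each by
#' [min_cross_distance()] on the feature matrix, and returns the first split
#' whose distance exceeds `threshold`, together with the full distance list
#' (useful for choosing a threshold from the distance distribution's upper
#' tail). If no candidate passes, the maximal-distance split is returned and
#' flagged.
#'
#' @param features A [new_mapped_dataset()], normally normalized so the
#'   threshold is in z-score units.
#' @param n Samples per side.
#' @param threshold Minimum cross-set distance for two sets to count as far
#'   apart (default 0.7).
#' @param n_candidates Number of random splits to score (default 10000).
#' @param seed Integer seed.
#' @return A list with `split` (a `split_spec` with provenance
#'   `far_apart(threshold, seed)` plus the achieved `distance` and a
#'   `met_threshold` flag) and `distances` (all candidate distances).
#' @export
far_apart_split <- function(features, n = 20L, threshold = 0.7,
                            n_candidates = 10000L, seed = 1L) {
  stopifnot(inherits(features, "mapped_dataset"))
  if (!is_count(n, min = 1L)) abort("`n` must be a positive integer.")
  nset <- nrow(features)
  if (2L * n > nset) {
    abort(sprintf("2 * n = %d exceeds the dataset size (%d).", 2L * n, nset))
  }
  if (!is_count(n_candidates, min = 1L)) abort("`n_candidates` must be positive.")
  m <- feature_matrix(features)

  cand <- local_seed(seed, {
    purrr::map(seq_len(n_candidates), function(i) {
      idx <- sample.int(nset, 2L * n)
      list(train = idx[seq_len(n)], val = idx[seq(n + 1L, 2L * n)])
    })
  })
  distances <- vapply(cand, function(s) {
    min_cross_distance(m[s$train, , drop = FALSE], m[s$val, , drop = FALSE])
  }, numeric(1))

  hit <- which(distances > threshold)
  if (length(hit) > 0L) {
    pick <- hit[1L]
    met <- TRUE
  } else {
    pick <- which.max(distances)
    met <- FALSE
  }
  split <- new_split_spec(cand[[pick]]$train, cand[[pick]]$val, list(
    type = "far_apart", threshold = threshold, seed = as.integer(seed),
    distance = distances[pick], met_threshold = met, candidate = pick
  ))
  list(split = split, distances = distances)
}

#' Random few-shot splits
#'
#' Generates `n_runs` independent splits in which a small training set of
#' `n_train` samples is drawn uniformly without replacement and the validation
#' set is the complement — the scarce-annotation regime where training-set
#' choice dominates downstream performance.
#'
#' @param features A [new_mapped_dataset()].
#' @param n_train Training-set size (< dataset size).
#' @param n_runs Number of splits (default 100).
#' @param seed Integer seed.
#' @return A list of `split_spec` objects with provenance
#'   `random(n_train, seed, run)`.
#' @export
random_few_shot_splits <- function(features, n_train = 4L, n_runs = 100L,
                                   seed = 1L) {
  stopifnot(inherits(features, "mapped_dataset"))
  nset <- nrow(features)
  if (!is_count(n_train, min = 1L) || n_train >= nset) {
    abort("`n_train` must be a positive integer smaller than the dataset size.")
  }
  if (!is_count(n_runs, min = 1L)) abort("`n_runs` must be a positive integer.")
  local_seed(seed, {
    purrr::map(seq_len(n_runs), function(run) {
      train <- sort(sample.int(nset, n_train))
      new_split_spec(train, setdiff(seq_len(nset), train), list(
        type = "random", n_train = n_train, seed = as.integer(seed), run = run
      ))
    })
  })
}
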