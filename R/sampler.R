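# Grid discretization of the feature space, union-of-hyperspheres sampling
# set, and FUS-minimized uniform sample selection.

#' Discretize a normalized feature space onto a regular grid
#'
#' Each z-scored feature axis is divided into cells of width
#' `w = (max - min) / nu`, and every sample is mapped to integer grid
#' coordinates by `floor(value / w)` (true floor, so negative values round
#' down). The scale `nu` is therefore the target number of cells spanning each
#' feature's observed range; larger `nu` gives a finer grid. Because of
#' undersampling, many samples share a grid cell — this collapsing is what
#' later allows uniform sampling of the occupied region. Alternatively a fixed
#' `cell_width` (scalar or per-axis) can be supplied, in which case `nu` is
#' ignored and `floor(value / cell_width)` is used directly.
#'
#' @param dataset A normalized [new_mapped_dataset()] (see
#'   [normalize_features()]).
#' @param nu Positive scale setting the number of grid cells per feature range
#'   (default 10).
#' @param cell_width Optional explicit cell width override.
#' @return A `grid_dataset`: list with `coords` (n x d integer matrix),
#'   `cell_width` (realized per-axis widths), `nu`, `source_ids`,
#'   `sample_ids`, `feature_cols`.
#' @export
discretize_features <- function(dataset, nu = 10, cell_width = NULL) {
  stopifnot(inherits(dataset, "mapped_dataset"))
  if (!is_normalized(dataset)) {
    abort("`dataset` must be normalized first (see `normalize_features()`).")
  }
  m <- feature_matrix(dataset)
  d <- ncol(m)
  if (is.null(cell_width)) {
    if (!is_number(nu) || nu <= 0) abort("`nu` must be a positive number.")
    rng <- apply(m, 2L, function(x) max(x) - min(x))
    if (any(rng == 0)) abort("A feature column has zero range; cannot set a cell width.")
    w <- rng / nu
  } else {
    if (any(cell_width <= 0)) abort("`cell_width` must be positive.")
    w <- rep_len(cell_width, d)
  }
  coords <- floor(sweep(m, 2L, w, "/"))
  storage.mode(coords) <- "integer"
  rownames(coords) <- NULL
  w <- unname(w)
  structure(
    list(
      coords = coords,
      cell_width = w,
      nu = if (is.null(cell_width)) nu else NA_real_,
      source_ids = dataset$source_id,
      sample_ids = dataset$sample_id,
      feature_cols = feature_cols(dataset)
    ),
    class = "grid_dataset"
  )
}

#' @export
print.grid_dataset <- function(x, ...) {
  cat(sprintf(
    "<grid_dataset> %d samples, %d axes, %d occupied cells (cell widths %s)\n",
    nrow(x$coords), ncol(x$coords),
    nrow(unique_rows(x$coords)),
    paste(signif(x$cell_width, 3), collapse = ", ")
  ))
  invisible(x)
}

# Unique rows of an integer matrix, in lexicographic order. Rows are encoded
# as a single number when the coordinate span allows exact representation.
unique_rows <- function(m) {
  if (nrow(m) == 0L) return(m)
  key <- encode_rows(m)
  u <- m[!duplicated(key), , drop = FALSE]
  u[do.call(order, as.data.frame(u)), , drop = FALSE]
}

encode_rows <- function(m) {
  lo <- apply(m, 2L, min)
  span <- apply(m, 2L, max) - lo + 1
  if (prod(span) < 2^52) {
    key <- rep(0, nrow(m))
    for (j in seq_len(ncol(m))) {
      key <- key * span[j] + (m[, j] - lo[j])
    }
    key
  } else {
    apply(m, 1L, paste, collapse = ",")
  }
}

#' Integer offsets of a discrete hypersphere
#'
#' All integer d-vectors with Euclidean norm at most `r` (a closed discrete
#' ball, so the union over data points leaves no interior holes).
#'
#' @param d Dimension (>= 1).
#' @param r Non-negative integer radius, in grid units.
#' @return An m x d integer matrix of offsets, in lexicographic order.
#' @export
ball_offsets <- function(d, r) {
  if (!is_count(d, min = 1L)) abort("`d` must be a positive integer.")
  if (!is_count(r)) abort("`r` must be a non-negative integer.")
  g <- as.matrix(expand.grid(rep(list(seq(-r, r)), d)))
  colnames(g) <- NULL
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

#' Build the sampling set
#'
#' Centers a discrete hypersphere of radius `r` on every occupied grid cell
#' and takes the union: a sparse estimate of the support of the feature
#' distribution, from which annotation candidates are drawn uniformly. With
#' radius 0 the sampling set is exactly the set of occupied cells.
#'
#' @param grid A `grid_dataset` from [discretize_features()].
#' @param r Non-negative integer radius in grid units (default 4).
#' @return A `sampling_set`: list with `points` (unique integer coordinates,
#'   lexicographically sorted) and `radius`.
#' @export
build_sampling_set <- function(grid, r = 4L) {
  stopifnot(inherits(grid, "grid_dataset"))
  if (nrow(grid$coords) == 0L) abort("Empty grid dataset.")
  if (!is_count(r)) abort("`r` must be a non-negative integer.")
  cells <- unique_rows(grid$coords)
  off <- ball_offsets(ncol(cells), r)
  pts <- cells[rep(seq_len(nrow(cells)), each = nrow(off)), , drop = FALSE] +
    off[rep(seq_len(nrow(off)), times = nrow(cells)), , drop = FALSE]
  structure(
    list(points = unique_rows(pts), radius = as.integer(r)),
    class = "sampling_set"
  )
}

#' @export
print.sampling_set <- function(x, ...) {
  cat(sprintf("<sampling_set> %d points, radius %d\n", nrow(x$points), x$radius))
  invisible(x)
}

#' Farthest Unselected Sample metric
#'
#' For every data point not in the selection, the Euclidean distance (in grid
#' coordinates) to the nearest selected point is computed; FUS is the largest
#' of these distances. Low FUS means the selection leaves no large uncovered
#' region of the occupied feature space. If every point is selected, FUS is 0.
#'
#' @param selected_indices Indices (1-based rows of `grid$coords`) of the
#'   selected samples; non-empty.
#' @param grid A `grid_dataset`.
#' @return The FUS value (>= 0).
#' @export
fus_metric <- function(selected_indices, grid) {
  stopifnot(inherits(grid, "grid_dataset"))
  n <- nrow(grid$coords)
  sel <- unique(as.integer(selected_indices))
  if (length(sel) == 0L) abort("`selected_indices` must be non-empty.")
  if (any(sel < 1L | sel > n)) abort("`selected_indices` out of range.")
  unsel <- setdiff(seq_len(n), sel)
  if (length(unsel) == 0L) return(0)
  um <- grid$coords[unsel, , drop = FALSE]
  d2min <- rep(Inf, length(unsel))
  for (s in sel) {
    diff <- sweep(um, 2L, grid$coords[s, ], "-")
    d2min <- pmin(d2min, rowSums(diff^2))
  }
  sqrt(max(d2min))
}

#' Draw one uniform selection from the sampling set
#'
#' Repeatedly draws points uniformly from the sampling set, maps each drawn
#' point to the nearest data sample (Euclidean distance in grid coordinates,
#' ties broken by lowest sample index), and accepts the sample unless it was
#' already selected or shares a `source_id` with an already-selected sample
#' (same-image exclusion against data leakage). Drawing continues until `k`
#' samples are accumulated.
#'
#' @param sset A `sampling_set`.
#' @param grid The `grid_dataset` the sampling set was built from.
#' @param k Number of samples to select (at most the number of distinct
#'   source ids).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_draws Redraw budget before the configuration is declared
#'   infeasible (default 1e6).
#' @return A `selection_result`: list with `selected_indices` (in selection
#'   order), `fus`, `seed`, `k`, `n_draws`, `sample_ids`, `source_ids`.
#' @export
draw_subset <- function(sset, grid, k, seed = 1L, max_draws = 1e6) {
  stopifnot(inherits(sset, "sampling_set"), inherits(grid, "grid_dataset"))
  n <- nrow(grid$coords)
  if (!is_count(k, min = 1L)) abort("`k` must be a positive integer.")
  n_sources <- length(unique(grid$source_ids))
  if (k > n_sources) {
    abort(sprintf(
      "Cannot select k = %d samples from %d distinct sources (same-image exclusion).",
      k, n_sources
    ))
  }
  tc <- t(grid$coords) # d x n, for fast per-draw distances
  npts <- nrow(sset$points)

  local_seed(seed, {
    selected <- integer(0)
    used_sources <- character(0)
    n_draws <- 0L
    batch <- max(256L, 4L * k)
    while (length(selected) < k) {
      if (n_draws >= max_draws) {
        abort(sprintf("Redraw budget (%g draws) exceeded; selection infeasible.", max_draws))
      }
      idx <- sample.int(npts, batch, replace = TRUE)
      for (i in idx) {
        n_draws <- n_draws + 1L
        p <- sset$points[i, ]
        nearest <- which.min(colSums((tc - p)^2))
        if (!(nearest %in% selected) &&
            !(grid$source_ids[nearest] %in% used_sources)) {
          selected <- c(selected, nearest)
          used_sources <- c(used_sources, grid$source_ids[nearest])
          if (length(selected) == k) break
        }
        if (n_draws >= max_draws) break
      }
    }
    structure(
      list(
        selected_indices = selected,
        fus = fus_metric(selected, grid),
        seed = as.integer(seed),
        k = as.integer(k),
        n_draws = n_draws,
        sample_ids = grid$sample_ids[selected],
        source_ids = grid$source_ids[selected]
      ),
      class = "selection_result"
    )
  })
}

#' Select the best subset by minimizing FUS
#'
#' Runs [draw_subset()] `n_trials` times with derived seeds `seed + 1, ...,
#' seed + n_trials` and returns the selection with the smallest FUS (ties
#' broken by the first trial attaining the minimum). A single uniform draw can
#' leave large holes in feature space by chance; minimizing FUS over many
#' independent draws removes such distortions.
#'
#' @inheritParams draw_subset
#' @param n_trials Number of independent draws to score (default 1000).
#' @return The best `selection_result`, with extra fields `n_trials`,
#'   `base_seed`, `trial_seeds` and `trial_fus` for replay.
#' @export
select_best_subset <- function(sset, grid, k, n_trials = 1000L, seed = 1L,
                               max_draws = 1e6) {
  if (!is_count(n_trials, min = 1L)) abort("`n_trials` must be a positive integer.")
  trial_seeds <- as.integer(seed) + seq_len(n_trials)
  best <- NULL
  trial_fus <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    res <- draw_subset(sset, grid, k, seed = trial_seeds[i], max_draws = max_draws)
    trial_fus[i] <- res$fus
    if (is.null(best) || res$fus < best$fus) best <- res
  }
  best$n_trials <- as.integer(n_trials)
  best$base_seed <- as.integer(seed)
  best$trial_seeds <- trial_seeds
  best$trial_fus <- trial_fus
  best
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> k = %d, FUS = %.4f, seed = %d%s\n",
    x$k, x$fus, x$seed,
    if (!is.null(x$n_trials)) sprintf(" (best of %d trials)", x$n_trials) else ""
  ))
  invisible(x)
}

#' @describeIn select_best_subset Tidy the selected samples into a tibble
#'   (one row per selected sample).
#' @method tidy selection_result
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(
    rank = seq_along(x$selected_indices),
    index = x$selected_indices,
    sample_id = x$sample_ids,
    source_id = x$source_ids
  )
}

#' @describeIn select_best_subset One-row summary of the selection.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    k = x$k,
    fus = x$fus,
    n_draws = x$n_draws,
    n_trials = x$n_trials %||% NA_integer_,
    seed = x$seed
  )
}
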