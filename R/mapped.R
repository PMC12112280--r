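#' Feature-mapped datasets
#'
#' A `mapped_dataset` is a tibble with one row per sample, a `sample_id` and
#' `source_id` column, and a set of feature columns (by default the four
#' morphometry features: contrast, noise, density, detrended heterogeneity).
#' Normalization statistics are carried as attributes so that new samples can
#' be projected into the same standardized space.
#'
#' @param tbl A tibble with `sample_id`, `source_id` and the feature columns.
#' @param feature_cols Character vector naming the feature columns, in the
#'   fixed order used by the sampler.
#' @param normalized Whether the feature columns are already z-scored.
#' @param norm_means,norm_stds Per-feature statistics used for z-scoring
#'   (population standard deviation).
#' @param detrend Optional heterogeneity detrend fit (see
#'   [detrend_heterogeneity()]).
#' @return The tibble with class `mapped_dataset` and the metadata attached.
#' @export
new_mapped_dataset <- function(tbl, feature_cols,
                               normalized = FALSE,
                               norm_means = NULL, norm_stds = NULL,
                               detrend = NULL) {
  tbl <- as_tibble(tbl)
  missing_cols <- setdiff(c("sample_id", "source_id", feature_cols), names(tbl))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing columns: %s.", paste(missing_cols, collapse = ", ")))
  }
  structure(
    tbl,
    feature_cols = feature_cols,
    normalized = normalized,
    norm_means = norm_means,
    norm_stds = norm_stds,
    detrend = detrend,
    class = c("mapped_dataset", class(tbl))
  )
}

#' @rdname new_mapped_dataset
#' @param x A `mapped_dataset`.
#' @export
feature_cols <- function(x) attr(x, "feature_cols", exact = TRUE)

#' @rdname new_mapped_dataset
#' @export
feature_matrix <- function(x) {
  stopifnot(inherits(x, "mapped_dataset"))
  m <- as.matrix(as.data.frame(x)[, feature_cols(x), drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' @rdname new_mapped_dataset
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized", exact = TRUE))

#' Z-score the feature columns of a mapped dataset
#'
#' Centers each feature column to mean zero and scales it to unit variance
#' (population convention). The per-column means and standard deviations are
#' stored on the result so the same affine map can be applied to new samples.
#'
#' @param dataset A [new_mapped_dataset()] tibble with at least two rows.
#' @return The dataset with standardized feature columns, `normalized = TRUE`,
#'   and `norm_means` / `norm_stds` attributes.
#' @export
normalize_features <- function(dataset) {
  stopifnot(inherits(dataset, "mapped_dataset"))
  if (nrow(dataset) < 2L) abort("Need at least 2 samples to normalize.")
  m <- feature_matrix(dataset)
  mu <- colMeans(m)
  sdev <- apply(m, 2L, pop_sd)
  zero <- which(sdev == 0)
  if (length(zero) > 0L) {
    abort(sprintf(
      "Feature column(s) with zero variance cannot be normalized: %s.",
      paste(colnames(m)[zero], collapse = ", ")
    ))
  }
  z <- sweep(sweep(m, 2L, mu), 2L, sdev, "/")
  out <- dataset
  for (j in seq_along(feature_cols(dataset))) {
    out[[feature_cols(dataset)[j]]] <- z[, j]
  }
  new_mapped_dataset(
    out,
    feature_cols = feature_cols(dataset),
    normalized = TRUE,
    norm_means = mu,
    norm_stds = sdev,
    detrend = attr(dataset, "detrend", exact = TRUE)
  )
}

#' @export
print.mapped_dataset <- function(x, ...) {
  cat(sprintf(
    "<mapped_dataset> %d samples x %d features (%s)%s\n",
    nrow(x), length(feature_cols(x)),
    paste(feature_cols(x), collapse = ", "),
    if (is_normalized(x)) " [normalized]" else ""
  ))
  NextMethod()
}
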