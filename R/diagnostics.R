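# Heterogeneity diagnostics: feature histograms and flatness of the selected
# subset versus the full collection, plus a PCA scatter view.

#' Compare feature distributions of a selection against the full dataset
#'
#' For each feature, histograms of the full dataset and of the selected subset
#' are computed on shared bins and normalized by their sums, and a flatness
#' statistic — normalized Shannon entropy, 1 for a perfectly flat histogram —
#' is reported per set. Uniform feature-space sampling should flatten the
#' selected histograms relative to the full data (more weight on atypical
#' samples); the entropy comparison quantifies that, as an indicator rather
#' than a guarantee, since one-dimensional histograms are projections of the
#' 4-D selection.
#'
#' @param full A [new_mapped_dataset()] for the whole collection.
#' @param selection A `selection_result`, or an integer vector of selected row
#'   indices.
#' @param bins Number of shared histogram bins per feature (default 20).
#' @return A `selection_diagnostics` object with `histograms` (tibble:
#'   feature, bin midpoints, normalized full/selected frequencies) and
#'   `entropy` (tibble: feature, set, normalized entropy).
#' @export
diagnostics_report <- function(full, selection, bins = 20L) {
  stopifnot(inherits(full, "mapped_dataset"))
  idx <- if (inherits(selection, "selection_result")) {
    selection$selected_indices
  } else {
    as.integer(selection)
  }
  if (any(idx < 1L | idx > nrow(full))) abort("Selection indices out of range.")
  m <- feature_matrix(full)

  hist_one <- function(values, breaks) {
    counts <- tabulate(
      findInterval(values, breaks, rightmost.closed = TRUE, all.inside = TRUE),
      nbins = length(breaks) - 1L
    )
    counts / sum(counts)
  }

  hists <- purrr::map(colnames(m), function(f) {
    v <- m[, f]
    breaks <- seq(min(v), max(v), length.out = bins + 1L)
    if (min(v) == max(v)) breaks <- seq(min(v) - 0.5, max(v) + 0.5, length.out = bins + 1L)
    tibble(
      feature = f,
      bin = seq_len(bins),
      mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      full = hist_one(v, breaks),
      selected = hist_one(v[idx], breaks)
    )
  })
  hists <- dplyr::bind_rows(hists)

  norm_entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p)) / log(bins)
  }
  entropy <- hists |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      full = norm_entropy(.data$full),
      selected = norm_entropy(.data$selected),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("full", "selected"),
                        names_to = "set", values_to = "entropy")

  structure(
    list(histograms = hists, entropy = entropy, bins = bins, n_selected = length(idx)),
    class = "selection_diagnostics"
  )
}

#' @export
print.selection_diagnostics <- function(x, ...) {
  cat(sprintf("<selection_diagnostics> %d selected samples, %d bins\n",
              x$n_selected, x$bins))
  print(tidyr::pivot_wider(x$entropy, names_from = "set", values_from = "entropy"))
  invisible(x)
}

#' @describeIn diagnostics_report Histogram tibble in long format.
#' @method tidy selection_diagnostics
#' @param x A `selection_diagnostics`.
#' @param ... Unused.
#' @export
tidy.selection_diagnostics <- function(x, ...) {
  tidyr::pivot_longer(x$histograms, c("full", "selected"),
                      names_to = "set", values_to = "frequency")
}

#' @describeIn diagnostics_report Overlaid full/selected histograms per
#'   feature.
#' @method autoplot selection_diagnostics
#' @param object A `selection_diagnostics`.
#' @export
autoplot.selection_diagnostics <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$frequency,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "feature value", y = "normalized frequency",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' PCA scatter of the feature space with the selection highlighted
#'
#' Projects the (preferably normalized) feature matrix onto its first two
#' principal components and marks the selected samples. Visualization aid
#' only.
#'
#' @inheritParams diagnostics_report
#' @return A ggplot object.
#' @export
plot_feature_space <- function(full, selection = integer(0)) {
  stopifnot(inherits(full, "mapped_dataset"))
  idx <- if (inherits(selection, "selection_result")) {
    selection$selected_indices
  } else {
    as.integer(selection)
  }
  pc <- prcomp(feature_matrix(full), center = !is_normalized(full),
               scale. = FALSE)
  df <- tibble(
    pc1 = pc$x[, 1],
    pc2 = pc$x[, 2],
    selected = seq_len(nrow(full)) %in% idx
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(data = df[!df$selected, ], colour = "steelblue",
                        alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = df[df$selected, ], colour = "red", size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
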