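#' Patch extraction specification
#'
#' @param window_size Side length of the square windows (default 256 px).
#' @param n_random Number of additional windows at random positions
#'   (default 2, giving the usual 7 windows per source image).
#' @param min_skeleton_length_px Minimum total skeleton arc length for a
#'   window to survive [filter_windows()] (default 100 px).
#' @param seed Integer seed for the random window positions.
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(window_size = 256L, n_random = 2L,
                       min_skeleton_length_px = 100, seed = 1L) {
  if (!is_count(window_size, min = 1L)) abort("`window_size` must be a positive integer.")
  if (!is_count(n_random)) abort("`n_random` must be a non-negative integer.")
  if (!is_number(min_skeleton_length_px) || min_skeleton_length_px < 0) {
    abort("`min_skeleton_length_px` must be >= 0.")
  }
  structure(
    list(
      window_size = as.integer(window_size),
      n_random = as.integer(n_random),
      min_skeleton_length_px = min_skeleton_length_px,
      seed = as.integer(seed)
    ),
    class = "patch_spec"
  )
}

#' Extract windows from a source image
#'
#' Returns `5 + n_random` square windows: one flush against each image corner,
#' a central window anchored at `(floor((H - w) / 2), floor((W - w) / 2))`,
#' and `n_random` windows at uniformly random valid positions (drawn with
#' replacement; they may overlap the others). Corners and the center capture
#' the illumination inhomogeneities typical of confocal imaging. Windows are
#' half-open `[r, r + w) x [c, c + w)` with 0-based origins.
#'
#' @param image Numeric source image matrix (both dimensions >= window size).
#' @param mask Binary vessel mask, same shape.
#' @param spec A [patch_spec()].
#' @param source_id Identifier recorded on every window.
#' @return A tibble with one row per window: `sample_id`, `source_id`, `kind`
#'   (corner / center / random), 0-based `origin_row` / `origin_col`, and
#'   list-columns `image` and `mask`.
#' @export
extract_windows <- function(image, mask, spec = patch_spec(),
                            source_id = "image") {
  assert_matrix_2d(image, "image")
  mask <- as_binary_mask(mask)
  assert_same_shape(image, mask)
  w <- spec$window_size
  h_img <- nrow(image)
  w_img <- ncol(image)
  if (h_img < w || w_img < w) {
    abort(sprintf("Image (%dx%d) is smaller than the window size (%d).",
                  h_img, w_img, w))
  }

  det_origins <- rbind(
    c(0L, 0L),
    c(0L, w_img - w),
    c(h_img - w, 0L),
    c(h_img - w, w_img - w),
    c((h_img - w) %/% 2L, (w_img - w) %/% 2L)
  )
  kinds <- c(rep("corner", 4L), "center")
  if (spec$n_random > 0L) {
    row_pos <- seq(0L, h_img - w)
    col_pos <- seq(0L, w_img - w)
    rand <- local_seed(spec$seed, cbind(
      row_pos[sample.int(length(row_pos), spec$n_random, replace = TRUE)],
      col_pos[sample.int(length(col_pos), spec$n_random, replace = TRUE)]
    ))
    det_origins <- rbind(det_origins, rand)
    kinds <- c(kinds, rep("random", spec$n_random))
  }

  rows <- purrr::map(seq_len(nrow(det_origins)), function(i) {
    r0 <- det_origins[i, 1L]
    c0 <- det_origins[i, 2L]
    list(
      image = image[(r0 + 1L):(r0 + w), (c0 + 1L):(c0 + w), drop = FALSE],
      mask = mask[(r0 + 1L):(r0 + w), (c0 + 1L):(c0 + w), drop = FALSE]
    )
  })

  tibble(
    sample_id = sprintf("%s_w%02d", source_id, seq_along(kinds)),
    source_id = source_id,
    kind = kinds,
    origin_row = as.integer(det_origins[, 1L]),
    origin_col = as.integer(det_origins[, 2L]),
    image = purrr::map(rows, "image"),
    mask = purrr::map(rows, "mask")
  )
}

#' Filter windows by vessel content
#'
#' Windows without enough vessel material are uninformative for annotation;
#' they are removed by thresholding the total skeleton arc length of the
#' window mask. The filter is monotone in vessel content and idempotent.
#'
#' @param samples A tibble of windows (see [extract_windows()]).
#' @param spec A [patch_spec()] carrying `min_skeleton_length_px`, or a bare
#'   numeric threshold.
#' @return The kept rows, in input order, with a `skeleton_length` column
#'   appended.
#' @export
filter_windows <- function(samples, spec = patch_spec()) {
  threshold <- if (inherits(spec, "patch_spec")) spec$min_skeleton_length_px else spec
  if (!is_number(threshold) || threshold < 0) abort("Filter threshold must be >= 0.")
  if (!is.data.frame(samples) || !("mask" %in% names(samples))) {
    abort("`samples` must be a data frame with a `mask` list-column.")
  }
  if (nrow(samples) == 0L) {
    samples$skeleton_length <- numeric(0)
    return(samples)
  }
  len <- if ("skeleton_length" %in% names(samples)) {
    samples$skeleton_length
  } else {
    vapply(samples$mask, function(m) skeleton_length(skeletonize_mask(m)), numeric(1))
  }
  samples$skeleton_length <- len
  samples[len >= threshold, , drop = FALSE]
}
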