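# The four morphometry features: vessel contrast, background noise sigma,
# skeleton density, and (detrended) medial-line intensity heterogeneity.

#' Vessel contrast
#'
#' Ratio of the mean intensity of vessel pixels to the mean intensity of
#' background pixels, `C = mean(I[vessel]) / mean(I[background])`. Invariant
#' to positive intensity scaling.
#'
#' @param image Numeric intensity matrix.
#' @param mask Binary vessel mask, same shape.
#' @param background_margin Pixels within this distance of the mask are
#'   excluded from the background (default 0: the background is the exact
#'   complement). A small margin guards against partial-volume pixels at
#'   vessel borders biasing the background mean.
#' @return Contrast ratio (dimensionless).
#' @export
compute_contrast <- function(image, mask, background_margin = 0) {
  assert_matrix_2d(image, "image")
  mask <- as_binary_mask(mask)
  assert_same_shape(image, mask)
  vessel <- mask == 1L
  bg <- if (background_margin > 0) {
    dilate_mask(mask, background_margin) == 0L
  } else {
    !vessel
  }
  if (!any(vessel)) abort("Mask has no vessel pixels; contrast undefined.")
  if (!any(bg)) abort("Mask has no background pixels; contrast undefined.")
  bg_mean <- mean(image[bg])
  if (bg_mean == 0) abort("Background mean intensity is zero; contrast undefined.")
  mean(image[vessel]) / bg_mean
}

#' Wavelet-based noise standard deviation
#'
#' Robust estimate of the standard deviation of additive Gaussian noise from
#' the image background. A single-level 2-D orthonormal Haar transform is
#' applied; diagonal detail coefficients whose full 2x2 spatial support lies
#' in the background (mask == 0, optionally with a margin around vessels) are
#' collected, and `sigma = median(|d|) / 0.6745` — the usual median absolute
#' deviation estimator in the wavelet domain. Restricting to background
#' coefficients prevents vessel structure from inflating the estimate.
#'
#' @inheritParams compute_contrast
#' @return Estimated noise standard deviation, in intensity units.
#' @export
estimate_noise_sigma <- function(image, mask = NULL, background_margin = 0) {
  assert_matrix_2d(image, "image")
  if (is.null(mask)) mask <- matrix(0L, nrow(image), ncol(image))
  mask <- as_binary_mask(mask)
  assert_same_shape(image, mask)
  if (background_margin > 0) mask <- dilate_mask(mask, background_margin)

  nr2 <- (nrow(image) %/% 2L) * 2L
  nc2 <- (ncol(image) %/% 2L) * 2L
  if (nr2 < 2L || nc2 < 2L) abort("Image too small for a wavelet level.")
  odd_r <- seq(1L, nr2, by = 2L)
  odd_c <- seq(1L, nc2, by = 2L)
  a <- image[odd_r, odd_c, drop = FALSE]
  b <- image[odd_r, odd_c + 1L, drop = FALSE]
  cc <- image[odd_r + 1L, odd_c, drop = FALSE]
  d <- image[odd_r + 1L, odd_c + 1L, drop = FALSE]
  diag_detail <- (a - b - cc + d) / 2

  fg <- mask[odd_r, odd_c, drop = FALSE] | mask[odd_r, odd_c + 1L, drop = FALSE] |
    mask[odd_r + 1L, odd_c, drop = FALSE] | mask[odd_r + 1L, odd_c + 1L, drop = FALSE]
  keep <- diag_detail[!fg]
  if (length(keep) < 16L) {
    abort("Fewer than 16 background wavelet coefficients; noise estimate unreliable.")
  }
  median(abs(keep)) / 0.6745
}

#' Skeleton density
#'
#' Total medial-line arc length divided by the image area: centerline pixels
#' per image pixel (units 1/px). Arc length follows the discrete 8-adjacency
#' convention of [skeleton_length()].
#'
#' @param skeleton Binary skeleton matrix.
#' @param image_shape Integer pair (rows, cols); must equal `dim(skeleton)`.
#' @return Density (>= 0).
#' @export
compute_density <- function(skeleton, image_shape = dim(skeleton)) {
  skeleton <- as_binary_mask(skeleton, "skeleton")
  if (!identical(dim(skeleton), as.integer(image_shape))) {
    abort("`image_shape` must equal the skeleton dimensions.")
  }
  skeleton_length(skeleton) / prod(as.numeric(image_shape))
}

#' Medial-line intensity heterogeneity
#'
#' The image is blurred with a unit-standard-deviation Gaussian (to suppress
#' extreme single-pixel values) and sampled along the medial lines. `h` is the
#' population standard deviation of the sampled values — the raw heterogeneity
#' — and `m` their mean, used later to remove the brightness trend.
#'
#' @param image Numeric intensity matrix.
#' @param skeleton Binary medial-line matrix with at least 2 pixels.
#' @param blur_sigma Gaussian blur standard deviation (default 1 px).
#' @return A list with elements `h` (standard deviation, intensity units) and
#'   `m` (mean medial intensity).
#' @export
compute_medial_heterogeneity <- function(image, skeleton, blur_sigma = 1) {
  assert_matrix_2d(image, "image")
  skeleton <- as_binary_mask(skeleton, "skeleton")
  assert_same_shape(image, skeleton, c("image", "skeleton"))
  if (sum(skeleton) < 2L) {
    abort("Skeleton must contain at least 2 pixels for a heterogeneity estimate.")
  }
  blurred <- gaussian_blur(image, sigma = blur_sigma)
  vals <- blurred[skeleton == 1L]
  list(h = pop_sd(vals), m = mean(vals))
}

#' Detrend medial-line heterogeneity across a collection
#'
#' Raw heterogeneity `h` correlates with the mean medial intensity `m`
#' (brighter vessels fluctuate more in absolute terms). An ordinary
#' least-squares straight line `h_m = a * m + b` is fitted across the
#' collection and the detrended heterogeneity is the residual
#' `h_detrended = h - (a * m + b)`. Residuals sum to zero. When all `m` are
#' identical the fit is degenerate: the slope is set to 0 and the intercept to
#' `mean(h)`, and the fit is flagged.
#'
#' @param collection A data frame with numeric columns `h` and `m` (one row
#'   per sample), or a list of `(h, m)` pairs.
#' @return A list with `fit` (slope `a`, intercept `b`, logical `degenerate`)
#'   and `het_detrended` (numeric vector of residuals, in input order).
#' @export
detrend_heterogeneity <- function(collection) {
  if (!is.data.frame(collection)) {
    collection <- dplyr::bind_rows(lapply(collection, as.data.frame))
  }
  if (!all(c("h", "m") %in% names(collection))) {
    abort("`collection` must have columns `h` and `m`.")
  }
  h <- collection$h
  m <- collection$m
  if (length(h) < 1L) abort("Empty collection.")
  if (length(unique(m)) < 2L) {
    fit <- list(slope = 0, intercept = mean(h), degenerate = TRUE)
    return(list(fit = fit, het_detrended = h - mean(h)))
  }
  ls <- lm(h ~ m)
  a <- unname(coef(ls)[2])
  b <- unname(coef(ls)[1])
  list(
    fit = list(slope = a, intercept = b, degenerate = FALSE),
    het_detrended = h - (a * m + b)
  )
}

#' Map a sample collection to the 4-D morphometry feature space
#'
#' Computes, for every sample, the vessel contrast, the wavelet noise sigma
#' estimated on the background, the skeleton density, and the medial-line
#' heterogeneity; then detrends the heterogeneity against the mean medial
#' intensity across the whole collection. The feature columns, in fixed order,
#' are `contrast`, `noise`, `density`, `het_detrended`.
#'
#' @param samples A tibble with list-columns `image` and `mask` plus
#'   `source_id` (as produced by [generate_collection()] or
#'   [extract_windows()]). An optional `sample_id` column is preserved.
#' @param background_margin Passed to [compute_contrast()] and
#'   [estimate_noise_sigma()].
#' @return A [new_mapped_dataset()] tibble (unnormalized) with columns
#'   `sample_id`, `source_id`, `contrast`, `noise`, `density`,
#'   `het_detrended`, `het_raw`, `medial_mean`; the detrend fit is attached as
#'   an attribute.
#' @export
compute_collection_features <- function(samples, background_margin = 0) {
  if (!is.data.frame(samples) || !all(c("image", "mask", "source_id") %in% names(samples))) {
    abort("`samples` must be a data frame with `image`, `mask` and `source_id` columns.")
  }
  if (nrow(samples) == 0L) abort("Empty sample collection.")
  ids <- if ("sample_id" %in% names(samples)) {
    samples$sample_id
  } else {
    sprintf("sample_%05d", seq_len(nrow(samples)))
  }

  per_sample <- purrr::map(seq_len(nrow(samples)), function(i) {
    tryCatch({
      img <- samples$image[[i]]
      msk <- as_binary_mask(samples$mask[[i]])
      sk <- skeletonize_mask(msk)
      het <- compute_medial_heterogeneity(img, sk)
      list(
        contrast = compute_contrast(img, msk, background_margin),
        noise = estimate_noise_sigma(img, msk, background_margin),
        density = compute_density(sk, dim(img)),
        h = het$h,
        m = het$m
      )
    }, error = function(e) {
      abort(sprintf("Feature computation failed for sample `%s`: %s",
                    ids[i], conditionMessage(e)))
    })
  })

  hm <- tibble(
    h = vapply(per_sample, function(s) s$h, numeric(1)),
    m = vapply(per_sample, function(s) s$m, numeric(1))
  )
  dt <- detrend_heterogeneity(hm)

  tbl <- tibble(
    sample_id = ids,
    source_id = samples$source_id,
    contrast = vapply(per_sample, function(s) s$contrast, numeric(1)),
    noise = vapply(per_sample, function(s) s$noise, numeric(1)),
    density = vapply(per_sample, function(s) s$density, numeric(1)),
    het_detrended = dt$het_detrended,
    het_raw = hm$h,
    medial_mean = hm$m
  )
  new_mapped_dataset(
    tbl,
    feature_cols = c("contrast", "noise", "density", "het_detrended"),
    detrend = dt$fit
  )
}
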