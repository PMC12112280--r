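#' Parameters for the synthetic vessel-image generator
#'
#' Bundles the controllable properties of a generated image: bright tubular
#' structures on a dark background, as in fluorescence microscopy of
#' vasculature. Each parameter maps to one of the four morphometry features
#' measured downstream: the vessel/background mean ratio drives contrast,
#' `noise_sigma` the wavelet noise estimate, the number and length of curves
#' the skeleton density, and `heterogeneity_amplitude` the medial-line
#' intensity heterogeneity.
#'
#' @param image_size Integer pair (rows, cols), each >= 16.
#' @param n_curves Number of vessel centerlines to draw (>= 0).
#' @param vessel_radius_px Tube radius in pixels (> 0).
#' @param vessel_mean_intensity Mean vessel intensity (must exceed the
#'   background mean).
#' @param background_mean_intensity Mean background intensity.
#' @param noise_sigma Standard deviation of additive i.i.d. Gaussian noise, in
#'   intensity units (>= 0).
#' @param heterogeneity_amplitude Standard deviation, in intensity units, of
#'   the smooth multiplicative intensity modulation applied along vessels
#'   (>= 0).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `vessel_params` list.
#' @export
vessel_params <- function(image_size = c(256L, 256L),
                          n_curves = 3L,
                          vessel_radius_px = 3,
                          vessel_mean_intensity = 150,
                          background_mean_intensity = 50,
                          noise_sigma = 10,
                          heterogeneity_amplitude = 0,
                          seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 16L)) {
    abort("`image_size` must be a pair of integers, each >= 16.")
  }
  if (!is_count(n_curves)) abort("`n_curves` must be a non-negative integer.")
  if (!is_number(vessel_radius_px) || vessel_radius_px <= 0) {
    abort("`vessel_radius_px` must be positive.")
  }
  if (vessel_mean_intensity <= background_mean_intensity) {
    abort("`vessel_mean_intensity` must exceed `background_mean_intensity` (bright vessels on dark background).")
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (!is_number(heterogeneity_amplitude) || heterogeneity_amplitude < 0) {
    abort("`heterogeneity_amplitude` must be >= 0.")
  }
  structure(
    list(
      image_size = as.integer(image_size),
      n_curves = as.integer(n_curves),
      vessel_radius_px = vessel_radius_px,
      vessel_mean_intensity = vessel_mean_intensity,
      background_mean_intensity = background_mean_intensity,
      noise_sigma = noise_sigma,
      heterogeneity_amplitude = heterogeneity_amplitude,
      seed = as.integer(seed)
    ),
    class = "vessel_params"
  )
}

#' An image/mask sample
#'
#' Container pairing a grayscale intensity patch with its binary vessel mask,
#' the identifier of the source image it came from, and the 0-based (row, col)
#' origin of the patch within that source.
#'
#' @param image Numeric matrix of intensities.
#' @param mask Binary matrix, same dimensions (values 0/1).
#' @param source_id Character scalar naming the source image.
#' @param origin Integer pair, 0-based top-left position in the source.
#' @param ... Extra fields (e.g. generator ground truth) stored alongside.
#' @return An `image_sample` list.
#' @export
image_sample <- function(image, mask, source_id, origin = c(0L, 0L), ...) {
  assert_matrix_2d(image, "image")
  mask <- as_binary_mask(mask)
  assert_same_shape(image, mask)
  structure(
    list(
      image = image, mask = mask,
      source_id = as.character(source_id),
      origin = as.integer(origin),
      ...
    ),
    class = "image_sample"
  )
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf(
    "<image_sample> %dx%d  source=%s  origin=(%d,%d)  vessel px=%d\n",
    nrow(x$image), ncol(x$image), x$source_id, x$origin[1], x$origin[2],
    sum(x$mask)
  ))
  invisible(x)
}

# Rasterize one smooth random curve: a cubic spline through a few uniformly
# random control points, sampled densely and rounded to the pixel grid.
# Returns list(pixels = kx2 integer matrix, length = polyline arc length).
draw_random_curve <- function(nr, nc, n_control = 4L, step = 0.25) {
  cr <- runif(n_control, 1, nr)
  cc <- runif(n_control, 1, nc)
  # chord-length parameterization
  tt <- c(0, cumsum(sqrt(diff(cr)^2 + diff(cc)^2)))
  if (tt[n_control] == 0) tt <- seq(0, 1, length.out = n_control)
  fr <- splinefun(tt, cr, method = "natural")
  fc <- splinefun(tt, cc, method = "natural")
  s <- seq(0, tt[n_control], by = step)
  pr <- fr(s)
  pc <- fc(s)
  # clip the smooth path to the image so curves never leave the frame
  pr <- pmin(pmax(pr, 1), nr)
  pc <- pmin(pmax(pc, 1), nc)
  len <- sum(sqrt(diff(pr)^2 + diff(pc)^2))
  pix <- unique(cbind(as.integer(round(pr)), as.integer(round(pc))))
  list(pixels = pix, length = len)
}

#' Generate one synthetic vessel image
#'
#' Draws `n_curves` smooth random centerlines (cubic splines through random
#' control points), dilates them by `vessel_radius_px` to form the binary
#' vessel mask, paints vessel pixels at the vessel mean intensity modulated by
#' a smooth random field (standard deviation `heterogeneity_amplitude` in
#' intensity units), paints the background at its mean, adds i.i.d. Gaussian
#' noise of standard deviation `noise_sigma`, and clips to the 0-255 intensity
#' range. Rasterization is binary (no anti-aliasing), so with zero noise and
#' zero heterogeneity the image takes exactly two values. Deterministic given
#' `params$seed`.
#'
#' @param params A [vessel_params()] object.
#' @param source_id Optional source identifier; defaults to a seed-derived
#'   name.
#' @return An [image_sample()] with extra fields `centerline` (binary matrix),
#'   `centerline_length` (total smooth arc length, px) and `params`.
#' @export
generate_vessel_image <- function(params, source_id = NULL) {
  stopifnot(inherits(params, "vessel_params"))
  nr <- params$image_size[1]
  nc <- params$image_size[2]
  if (2 * params$vessel_radius_px + 1 > min(nr, nc)) {
    abort("Image too small for the requested vessel radius.")
  }
  source_id <- source_id %||% sprintf("synthetic_%d", params$seed)

  local_seed(params$seed, {
    centerline <- matrix(0L, nr, nc)
    total_len <- 0
    if (params$n_curves > 0L) {
      for (i in seq_len(params$n_curves)) {
        cv <- draw_random_curve(nr, nc)
        centerline[cv$pixels] <- 1L
        total_len <- total_len + cv$length
      }
    }
    mask <- if (sum(centerline) > 0L) {
      px <- which(centerline == 1L, arr.ind = TRUE)
      stamp_disc(nr, nc, px[, 1L], px[, 2L], params$vessel_radius_px)
    } else {
      matrix(0L, nr, nc)
    }

    image <- matrix(params$background_mean_intensity, nr, nc)
    vessel_value <- rep(params$vessel_mean_intensity, sum(mask))
    if (params$heterogeneity_amplitude > 0 && sum(mask) > 0L) {
      field <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc),
                             sigma = max(4, min(nr, nc) / 16))
      field <- (field - mean(field)) / pop_sd(field)
      modulation <- 1 + (params$heterogeneity_amplitude /
                           params$vessel_mean_intensity) * field
      vessel_value <- params$vessel_mean_intensity * modulation[mask == 1L]
    }
    image[mask == 1L] <- vessel_value
    if (params$noise_sigma > 0) {
      image <- image + matrix(rnorm(nr * nc, sd = params$noise_sigma), nr, nc)
    }
    image <- pmin(pmax(image, 0), 255)

    image_sample(
      image, mask, source_id,
      centerline = centerline,
      centerline_length = total_len,
      params = params
    )
  })
}

default_param_ranges <- function() {
  list(
    n_curves = c(2, 5),
    vessel_radius_px = c(2, 4),
    vessel_mean_intensity = c(120, 200),
    background_mean_intensity = c(30, 70),
    noise_sigma = c(2, 20),
    heterogeneity_amplitude = c(0, 30)
  )
}

#' Generate a collection of synthetic samples
#'
#' Draws `n_samples` images with generator parameters sampled uniformly and
#' independently within the given ranges, and returns them together with their
#' generating parameters (including the realized total centerline length) so
#' that feature-recovery experiments can correlate measured features against
#' ground truth.
#'
#' @param n_samples Number of samples (>= 1).
#' @param param_ranges Named list of `(low, high)` ranges for the fields
#'   `n_curves`, `vessel_radius_px`, `vessel_mean_intensity`,
#'   `background_mean_intensity`, `noise_sigma`, `heterogeneity_amplitude`.
#'   Missing entries fall back to defaults; degenerate ranges (low == high)
#'   pin a parameter.
#' @param image_size Integer pair applied to every sample.
#' @param seed Integer seed for the whole collection.
#' @param duplicate_factor Number of consecutive samples sharing one
#'   `source_id` (default 1, i.e. all sources distinct); larger values exist
#'   to exercise same-source exclusion in the sampler.
#' @return A tibble with one row per sample: `sample_id`, `source_id`,
#'   list-columns `image` and `mask`, the generating parameters, the realized
#'   `centerline_length` and `centerline_density`, and the per-sample
#'   `sample_seed` (the generated row equals
#'   `generate_vessel_image(vessel_params(..., seed = sample_seed))`).
#' @export
generate_collection <- function(n_samples,
                                param_ranges = list(),
                                image_size = c(256L, 256L),
                                seed = 1L,
                                duplicate_factor = 1L) {
  if (!is_count(n_samples, min = 1L)) abort("`n_samples` must be a positive integer.")
  ranges <- utils::modifyList(default_param_ranges(), param_ranges)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2]) {
      abort(sprintf("Range for `%s` must be (low, high) with low <= high.", nm))
    }
  }
  if (max(ranges$background_mean_intensity) >= min(ranges$vessel_mean_intensity)) {
    abort("Background intensity range must lie strictly below the vessel intensity range.")
  }

  draws <- local_seed(seed, {
    tibble(
      n_curves = vapply(seq_len(n_samples), function(i) {
        lo <- as.integer(ranges$n_curves[1]); hi <- as.integer(ranges$n_curves[2])
        if (lo == hi) lo else sample(seq(lo, hi), 1L)
      }, integer(1)),
      vessel_radius_px = runif(n_samples, ranges$vessel_radius_px[1], ranges$vessel_radius_px[2]),
      vessel_mean_intensity = runif(n_samples, ranges$vessel_mean_intensity[1], ranges$vessel_mean_intensity[2]),
      background_mean_intensity = runif(n_samples, ranges$background_mean_intensity[1], ranges$background_mean_intensity[2]),
      noise_sigma = runif(n_samples, ranges$noise_sigma[1], ranges$noise_sigma[2]),
      heterogeneity_amplitude = runif(n_samples, ranges$heterogeneity_amplitude[1], ranges$heterogeneity_amplitude[2]),
      sample_seed = sample.int(2147483646L, n_samples)
    )
  })

  src <- sprintf("src_%05d", ceiling(seq_len(n_samples) / duplicate_factor))
  samples <- purrr::pmap(draws, function(n_curves, vessel_radius_px,
                                         vessel_mean_intensity,
                                         background_mean_intensity,
                                         noise_sigma, heterogeneity_amplitude,
                                         sample_seed) {
    generate_vessel_image(vessel_params(
      image_size = image_size,
      n_curves = n_curves,
      vessel_radius_px = vessel_radius_px,
      vessel_mean_intensity = vessel_mean_intensity,
      background_mean_intensity = background_mean_intensity,
      noise_sigma = noise_sigma,
      heterogeneity_amplitude = heterogeneity_amplitude,
      seed = sample_seed
    ))
  })

  tibble(
    sample_id = sprintf("sample_%05d", seq_len(n_samples)),
    source_id = src,
    image = purrr::map(samples, "image"),
    mask = purrr::map(samples, "mask"),
    draws[, c(
      "n_curves", "vessel_radius_px", "vessel_mean_intensity",
      "background_mean_intensity", "noise_sigma", "heterogeneity_amplitude"
    )],
    contrast_ratio = draws$vessel_mean_intensity / draws$background_mean_intensity,
    centerline_length = vapply(samples, function(s) s$centerline_length, numeric(1)),
    centerline_density = vapply(samples, function(s) s$centerline_length, numeric(1)) /
      prod(image_size),
    sample_seed = draws$sample_seed
  )
}

#' Generate an abstract feature cloud
#'
#' Samples a Gaussian mixture in feature space, bypassing images entirely.
#' Useful for testing the sampling machinery: uniform feature-space sampling
#' should over-represent rare, well-separated clusters relative to
#' frequency-proportional sampling.
#'
#' @param n_points Number of points (>= 1).
#' @param cluster_weights Probability vector over clusters (sums to 1).
#' @param cluster_centers List of equal-length numeric centers (typically
#'   4-D), or a clusters-by-dimensions matrix.
#' @param cluster_stds Positive per-cluster isotropic standard deviations
#'   (recycled if scalar).
#' @param seed Integer seed.
#' @return A [new_mapped_dataset()] tibble with columns `sample_id`, `source_id`
#'   (all distinct), `cluster`, and features `f1..fd` (unnormalized).
#' @export
generate_feature_cloud <- function(n_points,
                                   cluster_weights = c(0.95, 0.05),
                                   cluster_centers = list(c(0, 0, 0, 0), c(8, 8, 8, 8)),
                                   cluster_stds = 1,
                                   seed = 1L) {
  if (!is_count(n_points, min = 1L)) abort("`n_points` must be a positive integer.")
  if (abs(sum(cluster_weights) - 1) > 1e-8 || any(cluster_weights < 0)) {
    abort("`cluster_weights` must be a probability vector summing to 1.")
  }
  if (is.matrix(cluster_centers)) {
    cluster_centers <- lapply(seq_len(nrow(cluster_centers)),
                              function(i) cluster_centers[i, ])
  }
  dims <- lengths(cluster_centers)
  if (length(unique(dims)) != 1L) {
    abort("All `cluster_centers` must have the same dimension.")
  }
  d <- dims[1]
  ncl <- length(cluster_centers)
  if (length(cluster_weights) != ncl) {
    abort("`cluster_weights` and `cluster_centers` must have equal length.")
  }
  stds <- rep_len(cluster_stds, ncl)
  if (any(stds < 0)) abort("`cluster_stds` must be non-negative.")

  pts <- local_seed(seed, {
    assign <- sample.int(ncl, n_points, replace = TRUE, prob = cluster_weights)
    centers <- do.call(rbind, cluster_centers)
    coords <- centers[assign, , drop = FALSE] +
      matrix(rnorm(n_points * d), n_points, d) * stds[assign]
    list(assign = assign, coords = coords)
  })

  feats <- as_tibble(as.data.frame(pts$coords))
  names(feats) <- paste0("f", seq_len(d))
  tbl <- tibble(
    sample_id = sprintf("pt_%06d", seq_len(n_points)),
    source_id = sprintf("pt_%06d", seq_len(n_points)),
    cluster = pts$assign
  )
  tbl <- dplyr::bind_cols(tbl, feats)
  new_mapped_dataset(tbl, feature_cols = names(feats))
}
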