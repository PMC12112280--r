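# Internal helpers shared across modules.

# Run code with a private, reproducible RNG state (global stream untouched).
local_seed <- function(seed, code) {
  withr::with_seed(
    seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

assert_matrix_2d <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric 2-D matrix.", name))
  }
  invisible(x)
}

assert_same_shape <- function(a, b, names = c("image", "mask")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf(
      "`%s` (%s) and `%s` (%s) must have identical dimensions.",
      names[1], paste(dim(a), collapse = "x"),
      names[2], paste(dim(b), collapse = "x")
    ))
  }
  invisible(NULL)
}

# Coerce to a strict 0/1 integer matrix; anything nonzero counts as foreground.
as_binary_mask <- function(mask, name = "mask") {
  if (is.matrix(mask) && is.logical(mask)) storage.mode(mask) <- "integer"
  assert_matrix_2d(mask, name)
  out <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  out
}

# Shift a matrix by (dr, dc), filling vacated cells with 0:
# out[r, c] == m[r - dr, c - dc] where defined.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr)
  cs <- seq_len(nc)
  src_r <- rs - dr
  src_c <- cs - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[rs[ok_r], cs[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Reflected (symmetric, edge repeated) index lookup for boundary handling.
reflect_index <- function(idx, n) {
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  idx
}

#' Gaussian blur with reflect padding
#'
#' Separable Gaussian convolution. Boundaries are handled by symmetric
#' reflection (edge pixel repeated), so patch borders do not darken.
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation of the Gaussian kernel, in pixels.
#' @return Blurred matrix, same dimensions as `image`.
#' @export
gaussian_blur <- function(image, sigma = 1) {
  assert_matrix_2d(image, "image")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(image)
  nc <- ncol(image)
  # rows
  out <- matrix(0, nr, nc)
  for (o in seq(-r, r)) {
    out <- out + k[o + r + 1L] * image[reflect_index(seq_len(nr) + o, nr), , drop = FALSE]
  }
  # columns
  out2 <- matrix(0, nr, nc)
  for (o in seq(-r, r)) {
    out2 <- out2 + k[o + r + 1L] * out[, reflect_index(seq_len(nc) + o, nc), drop = FALSE]
  }
  out2
}

# Integer offsets (dr, dc) of a closed disc of the given (real) radius.
disc_offsets <- function(radius) {
  r <- as.integer(floor(radius))
  g <- expand.grid(dr = seq(-r, r), dc = seq(-r, r))
  keep <- g$dr^2 + g$dc^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# Binary dilation of a mask by a disc of the given radius (in pixels).
dilate_mask <- function(mask, radius) {
  m <- as_binary_mask(mask)
  if (radius <= 0 || sum(m) == 0L) return(m)
  px <- which(m == 1L, arr.ind = TRUE)
  stamp_disc(nrow(m), ncol(m), px[, 1L], px[, 2L], radius)
}

# Mark all pixels within `radius` of the given (row, col) centers.
stamp_disc <- function(nr, nc, rows, cols, radius) {
  off <- disc_offsets(radius)
  rr <- rep(rows, each = nrow(off)) + off[, 1L]
  cc <- rep(cols, each = nrow(off)) + off[, 2L]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  out <- matrix(0L, nr, nc)
  out[cbind(rr[ok], cc[ok])] <- 1L
  out
}

# Population (divide-by-N) standard deviation, the convention used throughout.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}
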