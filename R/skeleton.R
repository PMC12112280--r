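#' Skeletonize a binary mask
#'
#' Reduces a binary foreground to a one-pixel-wide, 8-connected medial line by
#' iterative Zhang-Suen thinning. The skeleton is always a subset of the input
#' foreground, and thinning is idempotent on one-pixel-wide lines. On tubular
#' structures (the intended domain) the number of connected components is
#' preserved; degenerate isolated blobs smaller than the thinning templates
#' (e.g. a bare 2x2 square) can disappear entirely, as with any parallel
#' thinning scheme of this family.
#'
#' @param mask Binary matrix (any nonzero value is foreground).
#' @return Integer 0/1 matrix of the same dimensions containing the medial
#'   lines.
#' @export
#' @examples
#' bar <- matrix(0L, 20, 60)
#' bar[8:12, 5:55] <- 1L
#' sk <- skeletonize_mask(bar)
#' sum(sk) # roughly the bar length
skeletonize_mask <- function(mask) {
  m <- as_binary_mask(mask)
  if (sum(m) == 0L) return(m)

  # Thin inside the foreground bounding box (plus a 1-px guard ring) only.
  px <- which(m == 1L, arr.ind = TRUE)
  r0 <- max(1L, min(px[, 1L]) - 1L)
  r1 <- min(nrow(m), max(px[, 1L]) + 1L)
  c0 <- max(1L, min(px[, 2L]) - 1L)
  c1 <- min(ncol(m), max(px[, 2L]) + 1L)
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  sub <- thin_zhang_suen(sub)
  out <- matrix(0L, nrow(m), ncol(m))
  out[r0:r1, c0:c1] <- sub
  out
}

# Parallel two-subiteration thinning (Zhang & Suen 1984), vectorized with
# matrix shifts. Neighbor labels follow the usual convention:
# p2 = N, p3 = NE, p4 = E, p5 = SE, p6 = S, p7 = SW, p8 = W, p9 = NW.
thin_zhang_suen <- function(m) {
  repeat {
    changed <- FALSE
    for (subiter in 1:2) {
      p2 <- shift_mat(m, 1L, 0L)
      p3 <- shift_mat(m, 1L, -1L)
      p4 <- shift_mat(m, 0L, -1L)
      p5 <- shift_mat(m, -1L, -1L)
      p6 <- shift_mat(m, -1L, 0L)
      p7 <- shift_mat(m, -1L, 1L)
      p8 <- shift_mat(m, 0L, 1L)
      p9 <- shift_mat(m, 1L, 1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      del <- if (subiter == 1L) {
        m == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p6) == 0L & (p4 * p6 * p8) == 0L
      } else {
        m == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p8) == 0L & (p2 * p6 * p8) == 0L
      }
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Total arc length of a skeleton
#'
#' Discrete arc length as the sum over all 8-adjacent skeleton pixel pairs of
#' the step length: 1 for axis-aligned steps and sqrt(2) for diagonal steps.
#' Each adjacency is counted once.
#'
#' @param skeleton Binary matrix of medial lines.
#' @return Arc length in pixels.
#' @export
skeleton_length <- function(skeleton) {
  m <- as_binary_mask(skeleton, "skeleton")
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr < 2L && nc < 2L) return(0)
  h <- if (nc >= 2L) sum(m[, -1L] & m[, -nc]) else 0L
  v <- if (nr >= 2L) sum(m[-1L, ] & m[-nr, ]) else 0L
  d1 <- if (nr >= 2L && nc >= 2L) sum(m[-1L, -1L] & m[-nr, -nc]) else 0L
  d2 <- if (nr >= 2L && nc >= 2L) sum(m[-1L, -nc] & m[-nr, -1L]) else 0L
  h + v + sqrt(2) * (d1 + d2)
}
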