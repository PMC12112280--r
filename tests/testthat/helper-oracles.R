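# Independent brute-force oracles used across the suite. These deliberately
# use the most naive formulation available so they cannot share bugs with the
# package implementations.

# Arc length by explicit enumeration of all pixel pairs.
oracle_arc_length <- function(skeleton) {
  px <- which(skeleton != 0, arr.ind = TRUE)
  if (nrow(px) < 2) return(0)
  total <- 0
  for (i in seq_len(nrow(px) - 1)) {
    for (j in seq(i + 1, nrow(px))) {
      dr <- abs(px[i, 1] - px[j, 1])
      dc <- abs(px[i, 2] - px[j, 2])
      if (dr <= 1 && dc <= 1) {
        total <- total + if (dr + dc == 2) sqrt(2) else 1
      }
    }
  }
  total
}

# FUS by a double loop over unselected and selected points.
oracle_fus <- function(selected, coords) {
  unsel <- setdiff(seq_len(nrow(coords)), selected)
  if (length(unsel) == 0) return(0)
  worst <- 0
  for (u in unsel) {
    best <- Inf
    for (s in selected) {
      best <- min(best, sqrt(sum((coords[u, ] - coords[s, ])^2)))
    }
    worst <- max(worst, best)
  }
  worst
}

# Discrete ball by exhaustive enumeration over the bounding cube.
oracle_ball <- function(d, r) {
  g <- as.matrix(expand.grid(rep(list(seq(-r, r)), d)))
  colnames(g) <- NULL
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

# 8-connected component count by flood fill.
oracle_n_components <- function(mask) {
  m <- mask != 0
  labels <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  for (start in which(m)) {
    if (labels[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      r <- (cur - 1) %% nrow(m) + 1
      c <- (cur - 1) %/% nrow(m) + 1
      for (k in seq_len(nrow(nbr))) {
        rr <- r + nbr$dr[k]
        cc <- c + nbr$dc[k]
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
            m[rr, cc] && labels[rr, cc] == 0L) {
          idx <- (cc - 1) * nrow(m) + rr
          labels[idx] <- comp
          queue <- c(queue, idx)
        }
      }
    }
  }
  comp
}

# Small deterministic tube mask fixture: a horizontal bar plus a separate
# diagonal tube, two components.
fixture_two_tubes <- function() {
  m <- matrix(0L, 64, 64)
  m[10:14, 5:55] <- 1L
  for (i in 0:25) m[(30 + i):(33 + i), 20 + i] <- 1L
  m
}
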