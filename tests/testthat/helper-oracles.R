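# Shared fixtures and independent oracles, built in code.

# Direct cell-by-cell domain score: loops over every matrix cell with
# the explicit midpoint/owner rule. Kept independent of the
# per-diagonal arithmetic used by tad_score() and the DP prefix sums.
naive_tad_score <- function(L, s, e, h) {
  n <- nrow(L)
  tot <- 0
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      d <- l - k
      if (d > h) next
      if (k >= s && l <= e) {
        tot <- tot + L[k, l]
      } else if (floor((k + l) / 2) >= s && floor((k + l) / 2) <= e) {
        tot <- tot - L[k, l]
      }
    }
  }
  tot
}

# Exhaustive-enumeration segmentation oracle over all 2^(n-1)
# boundary sets; scores each segmentation with naive_tad_score.
brute_force_segmentation <- function(L, h, min_tad_bins = 1L) {
  n <- nrow(L)
  best <- -Inf; best_b <- NULL; best_nd <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    b <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1L, b + 1L); ends <- c(b, n)
    if (any(ends - starts + 1L < min_tad_bins)) next
    if (any(ends - starts + 1L > h)) next
    sc <- sum(mapply(function(s, e) naive_tad_score(L, s, e, h),
                     starts, ends))
    nd <- length(starts)
    if (sc > best + 1e-9 ||
        (abs(sc - best) <= 1e-9 && nd < best_nd)) {
      best <- sc; best_b <- b; best_nd <- nd
    }
  }
  list(score = best, boundaries = best_b)
}

# symmetric random LPR matrix with zero diagonal
random_lpr <- function(n, sd = 1) {
  L <- matrix(0, n, n)
  up <- upper.tri(L)
  L[up] <- rnorm(sum(up), 0, sd)
  L[lower.tri(L)] <- t(L)[lower.tri(L)]
  L
}

# block-structured LPR matrix: +hi inside the given domains, -lo
# between them (planted segmentation signal)
planted_lpr <- function(n, ends, hi = 1, lo = 1) {
  starts <- c(1L, head(ends, -1) + 1L)
  ids <- rep(seq_along(ends), ends - starts + 1L)
  L <- matrix(-lo, n, n)
  same <- outer(ids, ids, "==")
  L[same] <- hi
  diag(L) <- 0
  L
}

# tiny deterministic two-block contact matrix
two_block_cm <- function(b1 = 5L, b2 = 5L, dense = 50, sparse = 2,
                         resolution = 40000L) {
  n <- b1 + b2
  m <- matrix(sparse, n, n)
  m[1:b1, 1:b1] <- dense
  m[(b1 + 1):n, (b1 + 1):n] <- dense
  diag(m) <- 0
  contact_matrix(m, resolution = resolution)
}
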