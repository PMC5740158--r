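# Domain scoring and optimal segmentation.
#
# The score of a candidate domain [s, e] adds the LPR of every
# intra-domain cell (s <= i <= j <= e, 0 < j - i <= h) and subtracts
# the LPR of every other cell whose midpoint falls inside the domain
# (0 < l - k <= h). Midpoints are real-valued; a half-integer midpoint
# sitting exactly on a shared boundary belongs to the left domain, so
# the owner bin of cell (k, l) is floor((k + l) / 2). Under this rule
# every cell is counted exactly once across an exhaustive segmentation
# and the total score is strictly additive over domains.

#' Score a candidate domain from an LPR matrix
#'
#' @param lpr_mat symmetric n x n LPR matrix (zeros outside the
#'   horizon / on invalid bins).
#' @param s,e domain start/end bins (1-based, inclusive, `s <= e`).
#' @param h maximal pair distance in bins for both the intra and the
#'   subtracted inter set.
#' @return the domain score (deterministic).
#' @export
tad_score <- function(lpr_mat, s, e, h) {
  n <- nrow(lpr_mat)
  if (s > e) stop("domain start exceeds end")
  stopifnot(s >= 1, e <= n)
  total <- 0
  for (d in seq_len(min(h, n - 1L))) {
    i_all <- seq_len(n - d)
    v <- lpr_mat[cbind(i_all, i_all + d)]
    # intra cells
    if (d <= e - s) {
      ii <- s:(e - d)
      total <- total + sum(v[ii])
    }
    # cells owned by a bin in [s, e]: owner(i, i+d) = i + floor(d/2)
    off <- d %/% 2L
    lo <- max(1L, s - off); hi <- min(n - d, e - off)
    if (lo <= hi) {
      owned <- sum(v[lo:hi])
      intra_part <- if (d <= e - s) sum(v[s:(e - d)]) else 0
      total <- total - (owned - intra_part)
    }
  }
  total
}

# Prefix structures for O(n * h) scoring inside the DP:
#  - cum_owner[b + 1]: cumulative sum over owner bins of all cell LPRs
#  - row_cum[i, j + 1]: cumulative LPR along row i
.score_prefix <- function(lpr_mat, h) {
  n <- nrow(lpr_mat)
  owner <- numeric(n)
  for (d in seq_len(min(h, n - 1L))) {
    i <- seq_len(n - d)
    o <- i + d %/% 2L
    owner[o] <- owner[o] + lpr_mat[cbind(i, i + d)]
  }
  row_cum <- cbind(0, t(apply(lpr_mat, 1L, cumsum)))
  list(cum_owner = c(0, cumsum(owner)), row_cum = row_cum, n = n)
}

# tad_score via the prefix structures; must equal tad_score() exactly
# up to float association (contract-tested).
.tad_score_fast <- function(pre, s, e, h) {
  intra <- 0
  if (e > s) {
    hi <- pmin(e, (s:(e - 1L)) + h)
    intra <- sum(pre$row_cum[cbind(s:(e - 1L), hi + 1L)] -
                 pre$row_cum[cbind(s:(e - 1L), (s:(e - 1L)) + 1L)])
  }
  2 * intra - (pre$cum_owner[e + 1L] - pre$cum_owner[s])
}

#' Optimal chromosome segmentation by dynamic programming
#'
#' Maximizes the total segmentation score (the sum of per-domain
#' scores) over all exhaustive segmentations whose domains have
#' between `min_tad_bins` and `h` bins. Ties are broken toward fewer
#' domains, then toward leftmost boundaries; the result is
#' deterministic. Complexity O(n * h) using prefix sums of the LPR
#' matrix over position and owner bin.
#'
#' @inheritParams tad_score
#' @param min_tad_bins minimal domain length in bins (default 3).
#' @param chrom,resolution metadata for the returned `Segmentation`.
#' @return list with `segmentation` and `score`.
#' @export
optimal_segmentation <- function(lpr_mat, h, min_tad_bins = 3L,
                                 chrom = "chr1", resolution = 40000L) {
  n <- nrow(lpr_mat)
  stopifnot(all(is.finite(lpr_mat)))
  if (n < min_tad_bins) {
    warning("chromosome shorter than min_tad_bins; returning one domain")
    seg <- segmentation(1L, n, n, chrom, resolution)
    return(list(segmentation = seg, score = tad_score(lpr_mat, 1L, n, h)))
  }
  pre <- .score_prefix(lpr_mat, h)
  maxlen <- min(h, n)
  NEG <- -Inf
  best <- c(0, rep(NEG, n))      # best[j + 1]: optimal score of prefix j
  ndom <- c(0L, rep(NA_integer_, n))
  back <- rep(NA_integer_, n + 1L)
  for (j in seq_len(n)) {
    intra <- 0
    cur <- NEG; curn <- NA_integer_; curs <- NA_integer_
    total_j <- pre$cum_owner[j + 1L]
    for (s in j:max(1L, j - maxlen + 1L)) {
      if (s < j)  # extend the last domain leftwards by row s
        intra <- intra + pre$row_cum[s, j + 1L] - pre$row_cum[s, s + 1L]
      if (j - s + 1L < min_tad_bins) next
      if (best[s] == NEG) next
      cand <- best[s] + 2 * intra - (total_j - pre$cum_owner[s])
      candn <- ndom[s] + 1L
      if (cand > cur ||
          (cand == cur && (candn < curn || (candn == curn && s < curs)))) {
        cur <- cand; curn <- candn; curs <- s
      }
    }
    best[j + 1L] <- cur; ndom[j + 1L] <- curn; back[j + 1L] <- curs
  }
  if (best[n + 1L] == NEG) {
    warning("no feasible segmentation under the size constraints; ",
            "returning one domain")
    seg <- segmentation(1L, n, n, chrom, resolution)
    return(list(segmentation = seg, score = tad_score(lpr_mat, 1L, n, h)))
  }
  starts <- integer(0); j <- n
  while (j >= 1L) {
    s <- back[j + 1L]
    starts <- c(s, starts)
    j <- s - 1L
  }
  ends <- c(starts[-1] - 1L, n)
  seg <- segmentation(starts, ends, n, chrom, resolution)
  list(segmentation = seg, score = best[n + 1L])
}

#' Insulation-style initial segmentation
#'
#' Simple initializer standing in for external boundary callers:
#' boundaries are placed at local minima of the mean contact count in a
#' sliding square of side `window_bins` below the diagonal. A uniform
#' matrix has no strict minima and yields a single domain. Minima too
#' close to an accepted boundary (or a chromosome end) to respect
#' `min_tad_bins` are dropped, deepest-first.
#'
#' @param cm a `ContactMatrix`.
#' @param window_bins side of the sliding square (default 10).
#' @param min_tad_bins minimal domain length in bins (default 3).
#' @return a `Segmentation`.
#' @export
initialize_segmentation <- function(cm, window_bins = 10L,
                                    min_tad_bins = 3L) {
  n <- n_bins(cm)
  w <- as.integer(window_bins)
  ins <- rep(NA_real_, n - 1L)
  for (b in seq_len(n - 1L)) {
    rows <- max(1L, b - w + 1L):b
    cols <- (b + 1L):min(n, b + w)
    rows <- rows[cm$valid[rows]]; cols <- cols[cm$valid[cols]]
    if (length(rows) && length(cols))
      ins[b] <- mean(cm$counts[rows, cols, drop = FALSE])
  }
  is_min <- vapply(seq_len(n - 1L), function(b) {
    if (is.na(ins[b])) return(FALSE)
    left <- if (b > 1L) ins[b - 1L] else NA_real_
    right <- if (b < n - 1L) ins[b + 1L] else NA_real_
    (!is.na(left) && ins[b] < left && (is.na(right) || ins[b] <= right)) ||
      (!is.na(right) && ins[b] < right && (is.na(left) || ins[b] <= left))
  }, logical(1))
  cand <- which(is_min)[order(ins[is_min])]
  accepted <- integer(0)
  for (b in cand) {
    ok <- b >= min_tad_bins && n - b >= min_tad_bins &&
      (!length(accepted) || min(abs(accepted - b)) >= min_tad_bins)
    if (ok) accepted <- c(accepted, b)
  }
  segmentation_from_boundaries(accepted, n, cm$chrom, cm$resolution)
}

#' Random initial segmentation
#'
#' Boundaries drawn uniformly with a target mean domain size;
#' reproducible under `seed`. Used to probe robustness of the final
#' calls to the initialization.
#'
#' @param cm a `ContactMatrix`.
#' @param mean_tad_bins target mean domain size in bins.
#' @param min_tad_bins minimal domain length in bins.
#' @param seed RNG seed (mandatory).
#' @export
random_segmentation <- function(cm, mean_tad_bins = 20L,
                                min_tad_bins = 3L, seed) {
  n <- n_bins(cm)
  with_seed(seed, {
    b <- integer(0); pos <- 0L
    while (TRUE) {
      step <- max(min_tad_bins,
                  stats::rpois(1, mean_tad_bins - min_tad_bins) +
                    min_tad_bins)
      pos <- pos + step
      if (pos >= n - min_tad_bins + 1L) break
      b <- c(b, pos)
    }
    segmentation_from_boundaries(b, n, cm$chrom, cm$resolution)
  })
}

#' Refine a segmentation by hard expectation-maximization
#'
#' Alternates mixture estimation on the current segmentation with
#' re-segmentation by dynamic programming until the segmentation stops
#' changing or `max_iter` is reached. Each round cannot decrease the
#' classification log-likelihood (see [classification_loglik()]).
#'
#' @inheritParams estimate_mixture
#' @param initial starting `Segmentation`.
#' @param max_iter iteration cap (default 10).
#' @param min_tad_bins minimal domain length in bins.
#' @param clip LPR clipping bound.
#' @return list with `segmentation`, `model`, `iterations`, `loglik`
#'   (per-iteration classification log-likelihood) and `converged`.
#' @export
em_refine <- function(cm, initial, h, pseudocount = 1, max_iter = 10L,
                      min_tad_bins = 3L, clip = 50) {
  seg <- initial
  ll_trace <- numeric(0)
  model <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    model <- estimate_mixture(cm, seg, h, pseudocount)
    lm_ <- lpr_matrix(cm, model, clip = clip)
    fit <- optimal_segmentation(lm_, h, min_tad_bins, cm$chrom,
                                cm$resolution)
    ll_trace <- c(ll_trace, classification_loglik(cm, fit$segmentation,
                                                  model))
    if (identical(fit$segmentation$starts, seg$starts)) {
      seg <- fit$segmentation
      converged <- TRUE
      break
    }
    seg <- fit$segmentation
  }
  list(segmentation = seg, model = model, iterations = iterations,
       loglik = ll_trace, converged = converged)
}
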