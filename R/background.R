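# Region-specific distance-decay background.
#
# Each leaf domain triangle, each merge rectangle and the residual
# inter-domain "Sky" get their own fit of log mean intensity versus
# log distance: a single power law (one line in log-log space) or a
# bi-linear model (two independent segments with a free breakpoint,
# no continuity constraint). Every valid cell at 1 <= d <= h is owned
# by exactly one fit region (innermost containing region, Sky
# otherwise); the expected matrix and residual map follow.

.line_fit <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(list(a = 0, b = y, sse = 0))
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  a <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  b <- my - a * mx
  list(a = a, b = b, sse = sum((y - a * x - b)^2))
}

#' Single power-law fit of an intensity profile
#'
#' Ordinary least squares of `log(I(d) + pseudocount)` on
#' `log(d * resolution)`; the slope is the power-law coefficient.
#'
#' @param profile data.frame with columns `d` (bins) and `mean`.
#' @param pseudocount added to the mean intensity before log.
#' @param resolution bin size in bp (distance scale of the intercept).
#' @return list with `a` (slope), `b` (intercept) and `sse`.
#' @export
fit_powerlaw <- function(profile, pseudocount = 1, resolution = 1) {
  stopifnot(nrow(profile) >= 1)
  f <- .line_fit(log(profile$d * resolution),
                 log(profile$mean + pseudocount))
  list(a = f$a, b = f$b, sse = f$sse)
}

#' Bi-linear (two-segment) power-law fit
#'
#' Exhaustive scan of candidate breakpoints over the observed
#' distances with at least 2 points per side; each segment is fitted
#' by independent OLS and the breakpoint minimizing the total SSE is
#' returned (ties: the smaller breakpoint). The scan uses incremental
#' sufficient statistics and is exactly equivalent to refitting both
#' segments at every candidate. Profiles with fewer than 4 support
#' distances fall back to a single segment (`single = TRUE`).
#'
#' @inheritParams fit_powerlaw
#' @return object of class `BiLinearFit`: list with `breakpoint_d`
#'   (last distance of the first segment, in bins; `NA` for single
#'   fits), `a1`, `b1`, `a2`, `b2`, `sse`, `n_points`, `single`.
#' @export
fit_bilinear <- function(profile, pseudocount = 1, resolution = 1) {
  profile <- profile[order(profile$d), , drop = FALSE]
  D <- nrow(profile)
  if (D == 0L) return(NULL)
  x <- log(profile$d * resolution)
  y <- log(profile$mean + pseudocount)
  if (D < 4L) {
    f <- .line_fit(x, y)
    return(structure(list(breakpoint_d = NA_integer_, a1 = f$a, b1 = f$b,
                          a2 = NA_real_, b2 = NA_real_, sse = f$sse,
                          n_points = D, single = TRUE),
                     class = "BiLinearFit"))
  }
  # incremental OLS statistics: segment SSE from cumulative sums
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  seg_sse <- function(lo, hi) {
    n <- hi - lo + 1L
    sx <- cx[hi] - if (lo > 1) cx[lo - 1] else 0
    sy <- cy[hi] - if (lo > 1) cy[lo - 1] else 0
    sxx <- cxx[hi] - if (lo > 1) cxx[lo - 1] else 0
    syy <- cyy[hi] - if (lo > 1) cyy[lo - 1] else 0
    sxy <- cxy[hi] - if (lo > 1) cxy[lo - 1] else 0
    vxx <- sxx - sx^2 / n
    vxy <- sxy - sx * sy / n
    vyy <- syy - sy^2 / n
    max(if (vxx > 0) vyy - vxy^2 / vxx else vyy, 0)
  }
  ks <- 2:(D - 2L)
  tot <- vapply(ks, function(k) seg_sse(1L, k) + seg_sse(k + 1L, D),
                numeric(1))
  k <- ks[which.min(tot)]   # which.min takes the first (smallest) tie
  f1 <- .line_fit(x[1:k], y[1:k])
  f2 <- .line_fit(x[(k + 1):D], y[(k + 1):D])
  structure(list(breakpoint_d = profile$d[k], a1 = f1$a, b1 = f1$b,
                 a2 = f2$a, b2 = f2$b, sse = f1$sse + f2$sse,
                 n_points = D, single = FALSE),
            class = "BiLinearFit")
}

#' Predict expected intensity from a fit
#' @param fit a `BiLinearFit` (or single-segment fallback).
#' @param d distances in bins (vectorized).
#' @param pseudocount,resolution as used in the fit.
#' @return expected intensity, floored at 0.
#' @export
predict_fit <- function(fit, d, pseudocount = 1, resolution = 1) {
  x <- log(d * resolution)
  yy <- if (isTRUE(fit$single)) fit$a1 * x + fit$b1
        else ifelse(d <= fit$breakpoint_d,
                    fit$a1 * x + fit$b1, fit$a2 * x + fit$b2)
  pmax(exp(yy) - pseudocount, 0)
}

# owner matrix: integer id per cell (leaf id, merge id, 0 = Sky,
# NA = diagonal / beyond horizon / invalid bin)
.owner_matrix <- function(forest, valid, h, use_merges = TRUE) {
  n <- forest$n_bins
  owner <- matrix(NA_integer_, n, n)
  for (d in seq_len(min(h, n - 1L))) {
    i <- seq_len(n - d); j <- i + d
    keep <- valid[i] & valid[j]
    owner[cbind(i[keep], j[keep])] <- 0L
  }
  for (nd in forest$nodes) {
    if (nd$level == 0L) {
      for (d in seq_len(min(h, nd$e - nd$s))) {
        i <- nd$s:(nd$e - d); j <- i + d
        keep <- valid[i] & valid[j]
        owner[cbind(i[keep], j[keep])] <- nd$id
      }
    } else if (use_merges) {
      ls <- nd$left_span; rs <- nd$right_span
      for (d in seq_len(min(h, rs[2] - ls[1]))) {
        lo <- max(ls[1], rs[1] - d); hi <- min(ls[2], rs[2] - d)
        if (lo > hi) next
        i <- lo:hi; j <- i + d
        keep <- valid[i] & valid[j]
        owner[cbind(i[keep], j[keep])] <- nd$id
      }
    }
  }
  owner[lower.tri(owner)] <- t(owner)[lower.tri(owner)]
  owner
}

#' Fit the full region-specific background model
#'
#' One decay fit per leaf domain (triangle profile), per merge node
#' (rectangle profile) and for the Sky (valid cells owned by no
#' region). Regions with empty support carry an absent fit.
#'
#' @param cm a `ContactMatrix`.
#' @param forest a `MergeForest` (possibly leaves-only).
#' @param h maximal distance in bins.
#' @param pseudocount added before logs (shared with the mixture).
#' @param bilinear fit two segments where the support allows
#'   (default), else force single power laws.
#' @param use_merges own cells of merge rectangles by their merge fit
#'   (default); if `FALSE` those cells fall to the Sky.
#' @return object of class `BackgroundModel`: fits keyed by region id
#'   ("0" = Sky), the cell owner matrix, and bookkeeping fields.
#' @export
build_background <- function(cm, forest, h, pseudocount = 1,
                             bilinear = TRUE, use_merges = TRUE) {
  owner <- .owner_matrix(forest, cm$valid, h, use_merges)
  fit_one <- function(profile) {
    if (!nrow(profile)) return(NULL)
    if (!bilinear) {
      f <- fit_powerlaw(profile, pseudocount, cm$resolution)
      structure(list(breakpoint_d = NA_integer_, a1 = f$a, b1 = f$b,
                     a2 = NA_real_, b2 = NA_real_, sse = f$sse,
                     n_points = nrow(profile), single = TRUE),
                class = "BiLinearFit")
    } else fit_bilinear(profile, pseudocount, cm$resolution)
  }
  fits <- list()
  for (nd in forest$nodes) {
    prof <- if (nd$level == 0L) {
      triangle_profile(cm, nd$s, nd$e, h)
    } else if (use_merges) {
      rect_profile(cm, nd$left_span, nd$right_span, h)
    } else NULL
    if (!is.null(prof))
      fits[as.character(nd$id)] <- list(fit_one(prof))
  }
  sky_cells <- which(owner == 0L & upper.tri(owner), arr.ind = TRUE)
  fits["0"] <- list(if (nrow(sky_cells))
    fit_one(intensity_profile(cm, sky_cells)) else NULL)
  structure(list(fits = fits, owner = owner, n = forest$n_bins,
                 resolution = cm$resolution, pseudocount = pseudocount,
                 h = h, valid = cm$valid, bilinear = bilinear),
            class = "BackgroundModel")
}

#' Expected contact matrix under a background model
#'
#' @param bg a `BackgroundModel`.
#' @return symmetric n x n matrix of expected counts (floored at 0);
#'   `NA` on cells owned by no region or whose region has an absent
#'   fit.
#' @export
expected_matrix <- function(bg) {
  n <- bg$n
  out <- matrix(NA_real_, n, n)
  for (key in names(bg$fits)) {
    fit <- bg$fits[[key]]
    if (is.null(fit)) next
    id <- as.integer(key)
    cells <- which(bg$owner == id & upper.tri(bg$owner), arr.ind = TRUE)
    if (!nrow(cells)) next
    d <- cells[, 2] - cells[, 1]
    v <- predict_fit(fit, d, bg$pseudocount, bg$resolution)
    out[cells] <- v
    out[cells[, c(2, 1), drop = FALSE]] <- v
  }
  out
}

#' Residual over-representation map
#'
#' `residual[i, j] = log(count + pc) - log(expected + pc)` for owned
#' valid cells; `NA` elsewhere. Log-ratio space makes the residuals
#' scale-free, matching the Normal model used by the enrichment test.
#'
#' @param cm a `ContactMatrix`.
#' @param expected matrix from [expected_matrix()].
#' @param pseudocount as used in the background fit.
#' @export
residual_map <- function(cm, expected, pseudocount = 1) {
  r <- log(cm$counts + pseudocount) - log(expected + pseudocount)
  r[is.na(expected)] <- NA_real_
  r
}

#' Root-mean-square residual over a cell set
#' @param residuals matrix from [residual_map()].
#' @param cells optional two-column matrix of (i, j) pairs; defaults
#'   to every non-missing cell of the upper triangle.
#' @export
fit_rmse <- function(residuals, cells = NULL) {
  v <- if (is.null(cells)) residuals[upper.tri(residuals)]
       else residuals[matrix(as.integer(cells), ncol = 2)]
  sqrt(mean(v^2, na.rm = TRUE))
}

#' RMSE ladder of nested background models
#'
#' Training-set RMSE of three models of increasing flexibility on the
#' same matrix and cells: one chromosome-wide power law; one single
#' power law per leaf domain (plus a Sky fit); and the full per-region
#' bi-linear model including merges. Comparable cells only (non-missing
#' under all three models).
#'
#' @param cm a `ContactMatrix`.
#' @param forest a `MergeForest` from [build_hierarchy()].
#' @param h maximal distance in bins.
#' @param pseudocount added before logs.
#' @return named numeric: `single`, `per_tad`, `bilinear`.
#' @export
model_ladder_rmse <- function(cm, forest, h, pseudocount = 1) {
  n <- n_bins(cm)
  seg1 <- segmentation(1L, n, n, cm$chrom, cm$resolution)
  bg_a <- build_background(cm, forest_from_segmentation(seg1), h,
                           pseudocount, bilinear = FALSE)
  bg_b <- build_background(cm, forest, h, pseudocount,
                           bilinear = FALSE, use_merges = FALSE)
  bg_c <- build_background(cm, forest, h, pseudocount, bilinear = TRUE)
  ra <- residual_map(cm, expected_matrix(bg_a), pseudocount)
  rb <- residual_map(cm, expected_matrix(bg_b), pseudocount)
  rc <- residual_map(cm, expected_matrix(bg_c), pseudocount)
  keep <- !is.na(ra) & !is.na(rb) & !is.na(rc) & upper.tri(ra)
  cells <- which(keep, arr.ind = TRUE)
  c(single = fit_rmse(ra, cells), per_tad = fit_rmse(rb, cells),
    bilinear = fit_rmse(rc, cells))
}
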