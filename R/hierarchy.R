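# Hierarchical merging of adjacent domains.
#
# Adjacent regions are merged greedily by the merge score alpha: the
# least-squares coefficient expressing how much the inter-region
# rectangle ("Merge") resembles the two regions' interior decay
# profiles versus the chromosome-wide inter-domain background ("Sky"),
#   I_merge(d) ~ alpha * I_tads(d) + (1 - alpha) * I_sky(d).

#' Mean intensity per distance over an arbitrary cell set
#'
#' @param cm a `ContactMatrix`.
#' @param cells two-column matrix of (i, j) bin pairs (1-based).
#' @return data.frame with columns `d`, `mean`, `n` (valid cells only;
#'   support = distances with at least one cell).
#' @export
intensity_profile <- function(cm, cells) {
  cells <- matrix(as.integer(cells), ncol = 2)
  i <- pmin(cells[, 1], cells[, 2]); j <- pmax(cells[, 1], cells[, 2])
  keep <- cm$valid[i] & cm$valid[j] & i != j
  i <- i[keep]; j <- j[keep]
  if (!length(i))
    return(data.frame(d = integer(0), mean = numeric(0), n = integer(0)))
  d <- j - i
  v <- cm$counts[cbind(i, j)]
  s <- rowsum(v, d); cnt <- rowsum(rep(1L, length(d)), d)
  data.frame(d = as.integer(rownames(s)), mean = s[, 1] / cnt[, 1],
             n = cnt[, 1])
}

# triangle profile of span [s, e]: per-distance sum/n over valid cells,
# capped at distance h
.triangle_stats <- function(cm, s, e, h) {
  dmax <- min(h, e - s)
  if (dmax < 1) return(data.frame(d = integer(0), sum = numeric(0),
                                  n = integer(0)))
  do.call(rbind, lapply(seq_len(dmax), function(d) {
    i <- s:(e - d); j <- i + d
    keep <- cm$valid[i] & cm$valid[j]
    data.frame(d = d, sum = sum(cm$counts[cbind(i[keep], j[keep])]),
               n = sum(keep))
  }))
}

.stats_to_profile <- function(st) {
  st <- st[st$n > 0, , drop = FALSE]
  data.frame(d = st$d, mean = st$sum / st$n, n = st$n)
}

#' Per-distance mean intensity of a domain triangle
#' @param cm a `ContactMatrix`.
#' @param s,e span bins (1-based inclusive).
#' @param h maximal distance in bins.
#' @export
triangle_profile <- function(cm, s, e, h) {
  .stats_to_profile(.triangle_stats(cm, s, e, h))
}

#' Per-distance mean intensity of a merge rectangle
#'
#' All pairs (i, j) with i in the left region and j in the right
#' region, up to distance h.
#'
#' @param cm a `ContactMatrix`.
#' @param left,right `c(start, end)` spans of the two regions
#'   (left entirely before right).
#' @param h maximal distance in bins.
#' @export
rect_profile <- function(cm, left, right, h) {
  dmax <- min(h, right[2] - left[1])
  ds <- seq_len(dmax)[seq_len(dmax) >= right[1] - left[2]]
  st <- do.call(rbind, lapply(ds, function(d) {
    lo <- max(left[1], right[1] - d); hi <- min(left[2], right[2] - d)
    if (lo > hi) return(NULL)
    i <- lo:hi
    j <- i + d
    keep <- cm$valid[i] & cm$valid[j]
    data.frame(d = d, sum = sum(cm$counts[cbind(i[keep], j[keep])]),
               n = sum(keep))
  }))
  if (is.null(st)) st <- data.frame(d = integer(0), sum = numeric(0),
                                    n = integer(0))
  .stats_to_profile(st)
}

# sky profile: valid cells at d <= h not covered by the region mask
.sky_profile <- function(cm, mask, h) {
  n <- n_bins(cm)
  st <- do.call(rbind, lapply(seq_len(min(h, n - 1L)), function(d) {
    i <- seq_len(n - d); j <- i + d
    keep <- cm$valid[i] & cm$valid[j] & !mask[cbind(i, j)]
    data.frame(d = d, sum = sum(cm$counts[cbind(i[keep], j[keep])]),
               n = sum(keep))
  }))
  .stats_to_profile(st)
}

#' Merge score alpha from three intensity profiles
#'
#' Least-squares alpha minimizing
#' `sum_d (I_merge(d) - alpha I_tads(d) - (1 - alpha) I_sky(d))^2`
#' over the common support, with the closed form
#' `alpha = sum (I_m - I_s)(I_t - I_s) / sum (I_t - I_s)^2`, clamped to
#' `[0, 1]` (the unclamped value is recorded).
#'
#' @param I_merge,I_tads,I_sky data.frames as returned by
#'   [intensity_profile()] and friends.
#' @return list with `alpha`, `alpha_raw`, `n_d`; `alpha` is `NA` when
#'   fewer than 2 common distances exist or the tads and sky profiles
#'   coincide on the support (candidate unmergeable).
#' @export
merge_alpha <- function(I_merge, I_tads, I_sky) {
  d <- intersect(intersect(I_merge$d, I_tads$d), I_sky$d)
  if (length(d) < 2)
    return(list(alpha = NA_real_, alpha_raw = NA_real_,
                n_d = length(d)))
  im <- I_merge$mean[match(d, I_merge$d)]
  it <- I_tads$mean[match(d, I_tads$d)]
  is_ <- I_sky$mean[match(d, I_sky$d)]
  denom <- sum((it - is_)^2)
  if (denom == 0)
    return(list(alpha = NA_real_, alpha_raw = NA_real_, n_d = length(d)))
  a <- sum((im - is_) * (it - is_)) / denom
  list(alpha = min(max(a, 0), 1), alpha_raw = a, n_d = length(d))
}

#' Build a leaves-only MergeForest from a segmentation
#'
#' @param seg a `Segmentation`.
#' @return a `MergeForest` whose nodes are the domains (level 0) and
#'   whose roots are the leaves; no merges.
#' @export
forest_from_segmentation <- function(seg) {
  nodes <- lapply(seq_along(seg$starts), function(k) {
    list(id = k, s = seg$starts[k], e = seg$ends[k], level = 0L,
         children = integer(0), alpha = NULL, alpha_raw = NULL,
         left_span = NULL, right_span = NULL)
  })
  structure(list(nodes = nodes, leaves = seq_along(seg$starts),
                 roots = seq_along(seg$starts), n_bins = seg$n_bins,
                 chrom = seg$chrom, resolution = seg$resolution),
            class = "MergeForest")
}

#' @export
print.MergeForest <- function(x, ...) {
  lv <- vapply(x$nodes, `[[`, integer(1), "level")
  cat(sprintf(
    "MergeForest: %d leaves, %d merges (max level %d), %d roots\n",
    sum(lv == 0), sum(lv > 0), max(lv), length(x$roots)))
  invisible(x)
}

#' Hierarchically merge adjacent domains
#'
#' Greedy loop: compute alpha for every adjacent pair of current
#' top-level regions whose union is at most `max_merge_bins`; merge the
#' pair with the largest alpha; remove the merge rectangle from the Sky
#' and repeat until no mergeable candidate remains. Ties within 1e-12
#' merge the leftmost pair; the whole construction is deterministic.
#' The pooled interior profile of a candidate uses the intra cells of
#' both children's spans; the Sky is recomputed after every merge.
#'
#' @param cm a `ContactMatrix`.
#' @param seg the leaf `Segmentation`.
#' @param max_merge_bins maximal merged span in bins.
#' @param h maximal profile distance in bins.
#' @param min_alpha minimal alpha to execute a merge (default 0, i.e.
#'   merge whenever alpha is defined).
#' @return a `MergeForest`: list of nodes (id, span, level, alpha,
#'   children, child spans), leaf ids and root ids.
#' @export
build_hierarchy <- function(cm, seg, max_merge_bins, h, min_alpha = 0) {
  forest <- forest_from_segmentation(seg)
  n <- n_bins(cm)
  # region mask over cells at d <= h: leaf triangles to start
  mask <- matrix(FALSE, n, n)
  for (k in seq_along(seg$starts)) {
    s <- seg$starts[k]; e <- seg$ends[k]
    for (d in seq_len(min(h, e - s))) {
      i <- s:(e - d)
      mask[cbind(i, i + d)] <- TRUE
    }
  }
  current <- forest$roots
  repeat {
    if (length(current) < 2) break
    sky <- .sky_profile(cm, mask, h)
    spans <- t(vapply(forest$nodes[current],
                      function(nd) c(nd$s, nd$e), numeric(2)))
    best_alpha <- -Inf; best_k <- NA_integer_; best_info <- NULL
    for (k in seq_len(length(current) - 1L)) {
      s1 <- spans[k, 1]; e1 <- spans[k, 2]
      s2 <- spans[k + 1, 1]; e2 <- spans[k + 1, 2]
      if (e2 - s1 + 1L > max_merge_bins) next
      imerge <- rect_profile(cm, c(s1, e1), c(s2, e2), h)
      itads <- .stats_to_profile(
        .pool_stats(.triangle_stats(cm, s1, e1, h),
                    .triangle_stats(cm, s2, e2, h)))
      a <- merge_alpha(imerge, itads, sky)
      if (is.na(a$alpha) || a$alpha < min_alpha) next
      if (a$alpha > best_alpha + 1e-12) {
        best_alpha <- a$alpha; best_k <- k; best_info <- a
      }
    }
    if (is.na(best_k)) break
    left_id <- current[best_k]; right_id <- current[best_k + 1L]
    left <- forest$nodes[[left_id]]; right <- forest$nodes[[right_id]]
    new_id <- length(forest$nodes) + 1L
    forest$nodes[[new_id]] <- list(
      id = new_id, s = left$s, e = right$e,
      level = 1L + max(left$level, right$level),
      children = c(left_id, right_id),
      alpha = best_info$alpha, alpha_raw = best_info$alpha_raw,
      left_span = c(left$s, left$e), right_span = c(right$s, right$e))
    # the merge rectangle leaves the Sky
    for (d in seq_len(min(h, right$e - left$s))) {
      lo <- max(left$s, right$s - d); hi <- min(left$e, right$e - d)
      if (lo > hi) next
      i <- lo:hi
      mask[cbind(i, i + d)] <- TRUE
    }
    current <- c(current[seq_len(best_k - 1L)], new_id,
                 current[-seq_len(best_k + 1L)])
    forest$roots <- current
  }
  forest$roots <- current
  forest
}

.pool_stats <- function(a, b) {
  st <- rbind(a, b)
  if (!nrow(st)) return(st)
  s <- rowsum(st$sum, st$d); n <- rowsum(st$n, st$d)
  data.frame(d = as.integer(rownames(s)), sum = s[, 1], n = n[, 1])
}
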