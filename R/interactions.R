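# Promoter-anchored enrichment calling from the residual map.
#
# For each promoter, the residuals in a 2 Mb window around its bin are
# summarized by a maximum-likelihood Normal (mu_i, sigma_i); every
# candidate bin within +/- 1 Mb gets z = (r - mu_i) / sigma_i and a
# one-sided p = 1 - Phi(z) (over-representation only). All
# promoter-bin tests of a run are pooled for Benjamini-Hochberg FDR.

#' Virtual-4C profile for an anchor bin
#'
#' Observed counts and background-expected values along the anchor row
#' for bins within `window_bp`; invalid/unowned bins are `NA`.
#'
#' @param cm a `ContactMatrix`.
#' @param expected matrix from [expected_matrix()].
#' @param anchor_bin 1-based anchor bin.
#' @param window_bp half-window in bp (default 1 Mb).
#' @return data.frame with `bin`, `distance_bp`, `observed`,
#'   `expected`.
#' @export
virtual_4c <- function(cm, expected, anchor_bin, window_bp = 1e6) {
  n <- n_bins(cm)
  w <- floor(window_bp / cm$resolution)
  bins <- max(1L, anchor_bin - w):min(n, anchor_bin + w)
  bins <- bins[bins != anchor_bin]
  obs <- cm$counts[anchor_bin, bins]
  obs[!cm$valid[bins] | !cm$valid[anchor_bin]] <- NA_real_
  data.frame(bin = bins,
             distance_bp = (bins - anchor_bin) * cm$resolution,
             observed = obs, expected = expected[anchor_bin, bins])
}

#' Residual enrichment statistics for one promoter
#'
#' @param residuals matrix from [residual_map()].
#' @param promoter_bin 1-based promoter bin.
#' @param resolution bin size in bp.
#' @param test_window_bp half-width of the tested window (default
#'   1 Mb).
#' @param fit_window_bp half-width of the window used to fit the
#'   Normal (mu_i, sigma_i) (default 2 Mb); the MLE (1/n) SD is used.
#' @param min_fit_cells minimal residual cells required in the fit
#'   window (default 30).
#' @param min_sigma promoters with fitted SD below this are skipped
#'   (flat residuals; default 1e-6).
#' @param min_dist_bins candidate bins must be at least this many bins
#'   from the promoter (default 2, avoiding diagonal bleed).
#' @return list of class `PromoterEnrichment` with `promoter_bin`,
#'   `mu`, `sigma`, `n_fit` and a data.frame `tests` (`bin`,
#'   `residual`, `z`, `p`); or an object of class `promoter_skip`
#'   carrying the reason when the promoter cannot be tested.
#' @export
promoter_enrichment <- function(residuals, promoter_bin, resolution,
                                test_window_bp = 1e6,
                                fit_window_bp = 2e6,
                                min_fit_cells = 30L, min_sigma = 1e-6,
                                min_dist_bins = 2L) {
  n <- nrow(residuals)
  fw <- floor(fit_window_bp / resolution)
  tw <- floor(test_window_bp / resolution)
  fit_bins <- max(1L, promoter_bin - fw):min(n, promoter_bin + fw)
  fit_bins <- fit_bins[fit_bins != promoter_bin]
  rfit <- residuals[promoter_bin, fit_bins]
  rfit <- rfit[!is.na(rfit)]
  skip <- function(reason)
    structure(list(reason = reason), class = "promoter_skip")
  if (length(rfit) < min_fit_cells)
    return(skip(sprintf("only %d residual cells in fit window",
                        length(rfit))))
  mu <- mean(rfit)
  sigma <- sqrt(mean((rfit - mu)^2))   # MLE (1/n) standard deviation
  if (sigma < min_sigma) return(skip("degenerate (flat) residuals"))
  cand <- max(1L, promoter_bin - tw):min(n, promoter_bin + tw)
  cand <- cand[abs(cand - promoter_bin) >= min_dist_bins]
  r <- residuals[promoter_bin, cand]
  keep <- !is.na(r)
  cand <- cand[keep]; r <- r[keep]
  z <- (r - mu) / sigma
  structure(list(promoter_bin = promoter_bin, mu = mu, sigma = sigma,
                 n_fit = length(rfit),
                 tests = data.frame(bin = cand, residual = r, z = z,
                                    p = stats::pnorm(z,
                                                     lower.tail = FALSE))),
            class = "PromoterEnrichment")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values with monotonicity enforcement (the minimum over
#' tails of `p * m / rank`).
#'
#' @param pvalues numeric vector of p-values.
#' @export
fdr_correct <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

# both bins inside the span of one node with level <= max_level?
.same_region_flag <- function(forest, max_level) {
  spans <- do.call(rbind, lapply(forest$nodes, function(nd)
    if (nd$level <= max_level) c(nd$s, nd$e) else NULL))
  function(i, j) {
    if (is.null(spans)) return(rep(FALSE, length(i)))
    lo <- pmin(i, j); hi <- pmax(i, j)
    vapply(seq_along(lo), function(k)
      any(spans[, 1] <= lo[k] & spans[, 2] >= hi[k]), logical(1))
  }
}

#' Call promoter-anchored over-represented interactions
#'
#' Full enrichment pipeline over a promoter set: residual map from the
#' background model, per-promoter Normal fits, pooled BH correction,
#' and emission of calls with `q < fdr_threshold`, annotated with
#' same-domain and same-first-merge flags from the forest. A gene with
#' several TSS entries is tested per TSS; calls are deduplicated by
#' (gene, enhancer bin) keeping the smallest q. Deterministic.
#'
#' @param cm a `ContactMatrix`.
#' @param bg a `BackgroundModel`.
#' @param forest the `MergeForest` used for the flags.
#' @param promoters a `PromoterSet`.
#' @param fdr_threshold q-value cutoff (default 0.01).
#' @inheritParams promoter_enrichment
#' @return data.frame of calls sorted by (gene, q): `gene`,
#'   `promoter_bin`, `enhancer_bin`, `distance_bp`, `residual`, `z`,
#'   `p`, `q`, `same_tad`, `same_first_merge`. Attribute "skipped"
#'   records promoters that could not be tested; attribute "n_tests"
#'   the pooled test count.
#' @export
call_interactions <- function(cm, bg, forest, promoters,
                              fdr_threshold = 0.01,
                              test_window_bp = 1e6,
                              fit_window_bp = 2e6,
                              min_fit_cells = 30L, min_dist_bins = 2L) {
  residuals <- residual_map(cm, expected_matrix(bg), bg$pseudocount)
  rows <- list(); skipped <- list()
  for (k in seq_len(nrow(promoters))) {
    pbin <- promoters$bin[k]
    if (pbin < 1 || pbin > n_bins(cm) || !cm$valid[pbin]) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene = promoters$gene[k], bin = pbin,
                   reason = "invalid promoter bin")
      next
    }
    enr <- promoter_enrichment(residuals, pbin, cm$resolution,
                               test_window_bp, fit_window_bp,
                               min_fit_cells,
                               min_dist_bins = min_dist_bins)
    if (inherits(enr, "promoter_skip")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene = promoters$gene[k], bin = pbin,
                   reason = enr$reason)
      next
    }
    tst <- enr$tests
    rows[[length(rows) + 1L]] <- data.frame(
      gene = promoters$gene[k], promoter_bin = pbin,
      enhancer_bin = tst$bin,
      distance_bp = abs(tst$bin - pbin) * cm$resolution,
      residual = tst$residual, z = tst$z, p = tst$p,
      stringsAsFactors = FALSE)
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(), bin = integer(), reason = character())
  empty <- data.frame(gene = character(), promoter_bin = integer(),
                      enhancer_bin = integer(), distance_bp = numeric(),
                      residual = numeric(), z = numeric(), p = numeric(),
                      q = numeric(), same_tad = logical(),
                      same_first_merge = logical())
  if (!length(rows)) {
    attr(empty, "skipped") <- skipped; attr(empty, "n_tests") <- 0L
    return(empty)
  }
  tab <- do.call(rbind, rows)
  tab$q <- fdr_correct(tab$p)           # pooled across the whole run
  n_tests <- nrow(tab)
  tab <- tab[tab$q < fdr_threshold, , drop = FALSE]
  if (nrow(tab)) {
    # dedup per (gene, enhancer bin), keep min q (stable order)
    tab <- tab[order(tab$gene, tab$enhancer_bin, tab$q,
                     tab$promoter_bin), , drop = FALSE]
    tab <- tab[!duplicated(tab[, c("gene", "enhancer_bin")]), ,
               drop = FALSE]
    tab$same_tad <- .same_region_flag(forest, 0L)(tab$promoter_bin,
                                                  tab$enhancer_bin)
    tab$same_first_merge <-
      .same_region_flag(forest, 1L)(tab$promoter_bin, tab$enhancer_bin)
    tab <- tab[order(tab$gene, tab$q, tab$enhancer_bin), , drop = FALSE]
    rownames(tab) <- NULL
  } else tab <- empty
  attr(tab, "skipped") <- skipped
  attr(tab, "n_tests") <- n_tests
  tab
}

#' Random promoter-proximal control interactions
#'
#' Independent Bernoulli selection of candidate bins within
#' `window_bp` of each promoter, mirroring the construction of a
#' random enhancer set; reproducible under `seed`.
#'
#' @param promoters a `PromoterSet`.
#' @param n_bins chromosome bin count.
#' @param resolution bin size in bp.
#' @param window_bp half-window (default 1 Mb).
#' @param prob per-bin selection probability (default 0.01).
#' @param seed RNG seed (mandatory).
#' @return data.frame with `gene`, `promoter_bin`, `bin`.
#' @export
random_control_interactions <- function(promoters, n_bins, resolution,
                                        window_bp = 1e6, prob = 0.01,
                                        seed) {
  w <- floor(window_bp / resolution)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(promoters)), function(k) {
      p <- promoters$bin[k]
      cand <- max(1L, p - w):min(n_bins, p + w)
      cand <- cand[cand != p]
      sel <- cand[stats::runif(length(cand)) < prob]
      if (!length(sel)) return(NULL)
      data.frame(gene = promoters$gene[k], promoter_bin = p, bin = sel,
                 stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
      return(data.frame(gene = character(), promoter_bin = integer(),
                        bin = integer()))
    do.call(rbind, out)
  })
}
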