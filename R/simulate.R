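# Synthetic Hi-C generator with known ground truth.
#
# Mean matrices are assembled from region-owned distance-decay curves
# (domain triangles, optional merge rectangles blending domain and Sky
# profiles with a target alpha, Sky elsewhere), optionally multiplied
# by planted enrichment folds, then observed through Poisson
# resampling (the default), multiplicative log-normal noise, or no
# noise at all. All randomness flows from a single seed in documented
# order: domain layout, decay parameters, enrichment placement, count
# noise.

#' Build and validate a simulation specification
#'
#' Defaults emulate a deeply sequenced mammalian Hi-C map at 40 Kb
#' resolution: contiguous domains of 200 Kb - 2 Mb, per-domain
#' power-law decay with a breakpoint in the 150 - 350 Kb range, a
#' weaker inter-domain ("Sky") decay, and Poisson count noise.
#'
#' @param n_bins chromosome length in bins.
#' @param resolution bin size in bp.
#' @param tads optional 2-column matrix of (start, end) bins (1-based,
#'   tiling `1..n_bins`); drawn from `tad_size_bins` when `NULL`.
#' @param tad_size_bins inclusive range of random domain sizes in bins.
#' @param tad_params optional list (one per domain) of explicit decay
#'   parameters `list(a1, b1, a2, b2, breakpoint_d)` in natural-log
#'   space over `log(d * resolution)`; drawn from `decay` when `NULL`.
#' @param decay ranges for random per-domain curves: `intra_I1`
#'   (mean count at one-bin distance), `intra_slope`, `bilinear`,
#'   `breakpoint_bp`, `slope2_delta` (second-segment steepening).
#' @param sky inter-domain decay: `slope` and `I1` (mean count of an
#'   inter-domain cell one bin apart).
#' @param merges optional list of `list(children = c(..), alpha = a)`
#'   building merge rectangles bottom-up; children index domains
#'   (1..K) and previously listed merges (K+1, ...). Rectangle means
#'   are `alpha * I_tads(d) + (1 - alpha) * I_sky(d)` with the pooled
#'   children triangle profile.
#' @param enrich planted enrichments: data.frame (`i`, `j`, `fold`)
#'   with folds >= 1, or `list(n, fold, min_d, max_d)` to place `n`
#'   intra-domain cells at random.
#' @param noise "poisson" (default), "lognormal" or "none".
#' @param lognormal_sd SD of the log-normal noise mode.
#' @param depth global scale ("read depth") multiplying all means.
#' @param mask_bins bins forced invalid (zeroed).
#' @return validated list of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_bins = 250L, resolution = 40000L,
                            tads = NULL, tad_size_bins = c(5L, 50L),
                            tad_params = NULL,
                            decay = list(intra_I1 = c(80, 150),
                                         intra_slope = c(-1.2, -0.7),
                                         bilinear = TRUE,
                                         breakpoint_bp = c(150e3, 350e3),
                                         slope2_delta = c(0.3, 0.7)),
                            sky = list(slope = -1.4, I1 = 25),
                            merges = NULL, enrich = NULL,
                            noise = c("poisson", "lognormal", "none"),
                            lognormal_sd = 0.3, depth = 1,
                            mask_bins = integer(0)) {
  noise <- match.arg(noise)
  if (!is.null(tads)) {
    tads <- matrix(as.integer(tads), ncol = 2)
    if (tads[1, 1] != 1L || tads[nrow(tads), 2] != n_bins ||
        any(tads[, 1] > tads[, 2]) ||
        (nrow(tads) > 1 && any(tads[-1, 1] != tads[-nrow(tads), 2] + 1L)))
      stop("tads must tile 1..n_bins without overlap")
  }
  if (is.data.frame(enrich)) {
    stopifnot(all(c("i", "j", "fold") %in% names(enrich)))
    if (any(enrich$fold < 1)) stop("enrichment folds must be >= 1")
  }
  if (depth <= 0) stop("depth must be positive")
  structure(list(n_bins = as.integer(n_bins),
                 resolution = as.integer(resolution), tads = tads,
                 tad_size_bins = as.integer(tad_size_bins),
                 tad_params = tad_params, decay = decay, sky = sky,
                 merges = merges, enrich = enrich, noise = noise,
                 lognormal_sd = lognormal_sd, depth = depth,
                 mask_bins = as.integer(mask_bins)),
            class = "SimulationSpec")
}

# curve evaluation: mean count at distance d (bins) for params in
# log-log space over log(d * resolution)
.curve_mean <- function(par, d, resolution) {
  x <- log(d * resolution)
  if (is.null(par$breakpoint_d) || is.na(par$breakpoint_d)) {
    exp(par$a1 * x + par$b1)
  } else {
    ifelse(d <= par$breakpoint_d, exp(par$a1 * x + par$b1),
           exp(par$a2 * x + par$b2))
  }
}

.draw_tads <- function(n_bins, size_range) {
  sizes <- integer(0); tot <- 0L
  while (tot < n_bins) {
    s <- sample(size_range[1]:size_range[2], 1L)
    sizes <- c(sizes, s); tot <- tot + s
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (tot - n_bins)
  if (sizes[length(sizes)] < size_range[1] && length(sizes) > 1) {
    sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] +
      sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  ends <- cumsum(sizes)
  cbind(c(1L, ends[-length(ends)] + 1L), ends)
}

.draw_tad_params <- function(k, decay, resolution) {
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  lapply(seq_len(k), function(i) {
    a1 <- runif1(decay$intra_slope)
    b1 <- log(runif1(decay$intra_I1)) - a1 * log(resolution)
    if (isTRUE(decay$bilinear)) {
      bp_d <- max(2L, round(runif1(decay$breakpoint_bp) / resolution))
      a2 <- a1 - runif1(decay$slope2_delta)
      # continuous at the breakpoint by construction
      b2 <- (a1 - a2) * log(bp_d * resolution) + b1
      list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, breakpoint_d = bp_d)
    } else list(a1 = a1, b1 = b1, a2 = NA_real_, b2 = NA_real_,
                breakpoint_d = NA_integer_)
  })
}

#' Simulate a Hi-C contact matrix with known ground truth
#'
#' @param spec a `SimulationSpec`.
#' @param seed RNG seed (mandatory; same seed, same matrix).
#' @return list with `matrix` (a `ContactMatrix`) and `truth`: the
#'   resolved domains, boundaries, decay parameters, merges, planted
#'   enrichments and the noise-free mean matrix.
#' @export
simulate_matrix <- function(spec, seed) {
  stopifnot(inherits(spec, "SimulationSpec"))
  with_seed(seed, {
    n <- spec$n_bins; res <- spec$resolution
    tads <- if (is.null(spec$tads))
      .draw_tads(n, spec$tad_size_bins) else spec$tads
    K <- nrow(tads)
    pars <- if (is.null(spec$tad_params))
      .draw_tad_params(K, spec$decay, res) else spec$tad_params
    stopifnot(length(pars) == K)
    skyb <- if (!is.null(spec$sky$b)) spec$sky$b else
      log(spec$sky$I1) - spec$sky$slope * log(res)
    skyp <- list(a1 = spec$sky$slope, b1 = skyb)

    mean_mat <- matrix(0, n, n)
    dgrid <- abs(col(mean_mat) - row(mean_mat))
    off <- dgrid > 0
    mean_mat[off] <- .curve_mean(skyp, dgrid[off], res)
    for (k in seq_len(K)) {
      s <- tads[k, 1]; e <- tads[k, 2]
      if (e > s) {
        idx <- s:e
        sub <- dgrid[idx, idx]
        block <- mean_mat[idx, idx]
        block[sub > 0] <- .curve_mean(pars[[k]], sub[sub > 0], res)
        mean_mat[idx, idx] <- block
      }
    }
    # merge rectangles: blend pooled children triangles with the Sky
    spans <- lapply(seq_len(K), function(k) tads[k, ])
    merges <- list()
    if (!is.null(spec$merges)) {
      for (m in spec$merges) {
        ch <- m$children
        stopifnot(length(ch) == 2, all(ch <= length(spans)))
        ls <- spans[[ch[1]]]; rs <- spans[[ch[2]]]
        stopifnot(rs[1] == ls[2] + 1L)
        for (d in seq_len(rs[2] - ls[1])) {
          lo <- max(ls[1], rs[1] - d); hi <- min(ls[2], rs[2] - d)
          if (lo > hi) next
          i <- lo:hi; j <- i + d
          # pooled mean over both children's span triangles at d
          tri_mean <- function(sp) {
            if (d > sp[2] - sp[1]) return(c(0, 0))
            ii <- sp[1]:(sp[2] - d)
            c(sum(mean_mat[cbind(ii, ii + d)]), length(ii))
          }
          t1 <- tri_mean(ls); t2 <- tri_mean(rs)
          if (t1[2] + t2[2] == 0) next
          it <- (t1[1] + t2[1]) / (t1[2] + t2[2])
          is_ <- .curve_mean(skyp, d, res)
          mean_mat[cbind(i, j)] <- m$alpha * it + (1 - m$alpha) * is_
          mean_mat[cbind(j, i)] <- mean_mat[cbind(i, j)]
        }
        spans[[length(spans) + 1L]] <- c(ls[1], rs[2])
        merges[[length(merges) + 1L]] <-
          list(children = ch, alpha = m$alpha, span = c(ls[1], rs[2]))
      }
    }
    mean_mat <- mean_mat * spec$depth

    enrich <- spec$enrich
    if (is.list(enrich) && !is.data.frame(enrich) &&
        !is.null(enrich$n)) {
      ids <- rep(seq_len(K), tads[, 2] - tads[, 1] + 1L)
      cand <- which(dgrid >= enrich$min_d & dgrid <= enrich$max_d &
                    upper.tri(dgrid), arr.ind = TRUE)
      cand <- cand[ids[cand[, 1]] == ids[cand[, 2]], , drop = FALSE]
      pick <- cand[sample(nrow(cand), min(enrich$n, nrow(cand))), ,
                   drop = FALSE]
      enrich <- data.frame(i = pick[, 1], j = pick[, 2],
                           fold = enrich$fold)
    }
    if (is.data.frame(enrich) && nrow(enrich)) {
      mean_mat[cbind(enrich$i, enrich$j)] <-
        mean_mat[cbind(enrich$i, enrich$j)] * enrich$fold
      mean_mat[cbind(enrich$j, enrich$i)] <-
        mean_mat[cbind(enrich$i, enrich$j)]
    }

    counts <- mean_mat
    if (spec$noise == "poisson") {
      up <- upper.tri(counts)
      counts[up] <- stats::rpois(sum(up), mean_mat[up])
      counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    } else if (spec$noise == "lognormal") {
      up <- upper.tri(counts)
      counts[up] <- mean_mat[up] *
        exp(stats::rnorm(sum(up), 0, spec$lognormal_sd))
      counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    }
    diag(counts) <- 0
    if (length(spec$mask_bins)) {
      counts[spec$mask_bins, ] <- 0
      counts[, spec$mask_bins] <- 0
    }
    cm <- contact_matrix(counts, chrom = "chrS", resolution = res)
    truth <- list(tads = tads, boundaries = tads[-K, 2],
                  tad_params = pars, sky = skyp, merges = merges,
                  enrich = if (is.data.frame(enrich)) enrich else NULL,
                  mean_matrix = mean_mat)
    list(matrix = cm, truth = truth)
  })
}

#' Poisson-resample a fitted background model
#'
#' Draws every owned cell from a Poisson distribution with the
#' expected mean, enabling the closed loop "fit, resample, refit".
#' Masked bins stay zero and invalid.
#'
#' @param bg a `BackgroundModel`.
#' @param seed RNG seed (mandatory).
#' @return a `ContactMatrix`.
#' @export
simulate_from_background <- function(bg, seed) {
  exp_mat <- expected_matrix(bg)
  exp_mat[is.na(exp_mat)] <- 0
  n <- bg$n
  with_seed(seed, {
    counts <- matrix(0, n, n)
    up <- upper.tri(counts)
    counts[up] <- stats::rpois(sum(up), exp_mat[up])
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    contact_matrix(counts, chrom = "chrS", resolution = bg$resolution,
                   valid = bg$valid)
  })
}

#' Read a simulation spec from YAML
#' @param path YAML file with `simulation_spec()` fields.
#' @export
read_sim_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tads)) y$tads <- matrix(unlist(y$tads), ncol = 2,
                                         byrow = TRUE)
  if (!is.null(y$enrich) && !is.null(y$enrich$i))
    y$enrich <- as.data.frame(y$enrich)
  do.call(simulation_spec, y)
}

#' The default simulation fixture shipped with the package
#' @return a `SimulationSpec` read from `inst/extdata`.
#' @export
default_sim_spec <- function() {
  read_sim_spec(system.file("extdata", "default_sim.yaml",
                            package = "hicdomains", mustWork = TRUE))
}
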