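#' Log-Normal density
#'
#' Density of the log-Normal distribution with log-scale mean `mu` and
#' log-scale standard deviation `sigma`:
#' \deqn{P(x) = \frac{1}{x \sigma \sqrt{2\pi}}
#'   e^{-(\log x - \mu)^2 / 2\sigma^2}}
#' (natural log). Thin wrapper over [stats::dlnorm()] with strict
#' domain checks; callers must add the pseudocount first so that x > 0.
#'
#' @param x positive real (vectorized).
#' @param mu,sigma log-scale mean and SD; `sigma > 0`.
#' @param log return log-density.
#' @export
lognormal_density <- function(x, mu, sigma, log = FALSE) {
  if (any(x <= 0)) stop("lognormal_density requires x > 0 ",
                        "(apply the pseudocount first)")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  stats::dlnorm(x, meanlog = mu, sdlog = sigma, log = log)
}

#' Construct a DistanceMixtureModel from a parameter table
#'
#' Six parameters per distance d (in bins): intra-domain and
#' inter-domain log-Normal (mu, sigma) plus the two mixture priors.
#'
#' @param params data.frame with columns `d`, `mu_intra`, `sigma_intra`,
#'   `mu_inter`, `sigma_inter`, `prior_intra`, `prior_inter`.
#' @param pseudocount value added to counts before taking logs.
#' @export
mixture_model <- function(params, pseudocount = 1) {
  need <- c("d", "mu_intra", "sigma_intra", "mu_inter", "sigma_inter",
            "prior_intra", "prior_inter")
  stopifnot(all(need %in% names(params)))
  params <- params[order(params$d), need]
  if (any(params$sigma_intra <= 0) || any(params$sigma_inter <= 0))
    stop("sigma parameters must be > 0")
  if (any(abs(params$prior_intra + params$prior_inter - 1) > 1e-8))
    stop("priors must sum to 1 at every distance")
  structure(list(params = params, h = max(params$d),
                 pseudocount = pseudocount),
            class = "DistanceMixtureModel")
}

#' @export
print.DistanceMixtureModel <- function(x, ...) {
  cat(sprintf(
    "DistanceMixtureModel: h = %d bins, pseudocount = %g, 6 par/distance\n",
    x$h, x$pseudocount))
  invisible(x)
}

# per-distance cell extraction shared by estimate/likelihood code:
# returns list of (d, logx, intra, i, j) for valid cells at 1 <= d <= h
.distance_cells <- function(cm, seg, h, pseudocount) {
  n <- n_bins(cm)
  ids <- domain_ids(seg)
  lapply(seq_len(min(h, n - 1L)), function(d) {
    i <- seq_len(n - d); j <- i + d
    keep <- cm$valid[i] & cm$valid[j]
    i <- i[keep]; j <- j[keep]
    list(d = d, i = i, j = j,
         logx = log(cm$counts[cbind(i, j)] + pseudocount),
         intra = ids[i] == ids[j])
  })
}

#' Estimate the per-distance two-component mixture
#'
#' Maximum-likelihood estimation of the six parameters per distance
#' from a contact matrix annotated with a (possibly noisy) domain
#' segmentation: mu/sigma are the mean and sample SD (ddof = 1) of
#' log(count + pseudocount) over valid intra-domain (resp.
#' inter-domain) cells at distance d; the intra prior is the fraction
#' of valid cells at d that are intra-domain. A class with fewer than
#' `min_samples` cells at some distance inherits its mean/SD by
#' linear interpolation over log d between the nearest well-sampled
#' distances of that class (nearest value beyond the ends); priors
#' are always taken from the observed cell counts.
#'
#' @param cm a `ContactMatrix`.
#' @param seg a `Segmentation` covering the matrix.
#' @param h maximal distance in bins (>= 1).
#' @param pseudocount added to counts before log (default 1).
#' @param min_samples minimal cells per class per distance (default 30).
#' @param sigma_floor lower bound on fitted SDs (default 1e-3).
#' @param prior_clip priors clipped to `[prior_clip, 1 - prior_clip]`.
#' @return a `DistanceMixtureModel`.
#' @export
estimate_mixture <- function(cm, seg, h, pseudocount = 1,
                             min_samples = 30L, sigma_floor = 1e-3,
                             prior_clip = 1e-4) {
  stopifnot(h >= 1)
  cells <- .distance_cells(cm, seg, h, pseudocount)
  stat1 <- function(x) if (length(x)) mean(x) else NA_real_
  stat2 <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  tab <- do.call(rbind, lapply(cells, function(cl) {
    a <- cl$logx[cl$intra]; b <- cl$logx[!cl$intra]
    data.frame(d = cl$d, mu_intra = stat1(a), sigma_intra = stat2(a),
               mu_inter = stat1(b), sigma_inter = stat2(b),
               n_intra = length(a), n_inter = length(b))
  }))
  if (all(tab$n_inter == 0))
    stop("degenerate annotation: no inter-domain cells at any distance")
  # per-class smoothing: sparse distances inherit mu/sigma by linear
  # interpolation over log d from the class's well-sampled distances
  smooth_class <- function(cols, nn) {
    ok <- nn >= min_samples & !is.na(tab[[cols[2]]])
    if (!any(ok))
      stop("no distance has >= ", min_samples, " cells in the ",
           sub("_.*", "", sub("mu_", "", cols[1])),
           " class; matrix too small or segmentation degenerate")
    for (col in cols) {
      if (all(ok)) next
      tab[[col]][!ok] <<- if (sum(ok) == 1L) tab[[col]][ok] else
        stats::approx(log(tab$d[ok]), tab[[col]][ok],
                      xout = log(tab$d[!ok]), rule = 2)$y
    }
  }
  smooth_class(c("mu_intra", "sigma_intra"), tab$n_intra)
  smooth_class(c("mu_inter", "sigma_inter"), tab$n_inter)
  prior <- tab$n_intra / (tab$n_intra + tab$n_inter)
  prior[!is.finite(prior)] <- 0.5    # distances with no valid cell
  tab$prior_intra <- pmin(pmax(prior, prior_clip), 1 - prior_clip)
  tab$prior_inter <- 1 - tab$prior_intra
  tab$sigma_intra <- pmax(tab$sigma_intra, sigma_floor)
  tab$sigma_inter <- pmax(tab$sigma_inter, sigma_floor)
  mixture_model(tab, pseudocount = pseudocount)
}

.model_row <- function(model, d) {
  d <- as.integer(d)
  if (any(d < 1 | d > model$h)) stop("distance outside model range 1..",
                                     model$h)
  model$params[d, ]  # params sorted with d = 1..h
}

#' Posterior probability that a cell is intra-domain
#'
#' Bayes' law over the two log-Normal sub-models at distance d:
#' `P_d(intra | N) = P_d(intra) L_intra / (P_d(intra) L_intra +
#'  P_d(inter) L_inter)` with likelihoods evaluated at
#' `N + pseudocount`.
#'
#' @param N observed count(s) (>= 0).
#' @param d distance in bins (scalar or vector matching N).
#' @param model a `DistanceMixtureModel`.
#' @return probability in `[0, 1]`.
#' @export
posterior_intra <- function(N, d, model) {
  p <- .model_row(model, d)
  x <- N + model$pseudocount
  la <- log(p$prior_intra) +
    stats::dlnorm(x, p$mu_intra, p$sigma_intra, log = TRUE)
  lb <- log(p$prior_inter) +
    stats::dlnorm(x, p$mu_inter, p$sigma_inter, log = TRUE)
  1 / (1 + exp(lb - la))
}

#' Log-posterior ratio (LPR) of the intra vs inter sub-models
#'
#' `LPR_d(N) = log(P_d(intra | N) / P_d(inter | N))`, clipped to
#' `+/- clip` so that no single cell can dominate a domain score.
#'
#' @inheritParams posterior_intra
#' @param clip symmetric clipping bound (default 50).
#' @export
lpr <- function(N, d, model, clip = 50) {
  p <- .model_row(model, d)
  x <- N + model$pseudocount
  r <- log(p$prior_intra) - log(p$prior_inter) +
    stats::dlnorm(x, p$mu_intra, p$sigma_intra, log = TRUE) -
    stats::dlnorm(x, p$mu_inter, p$sigma_inter, log = TRUE)
  pmin(pmax(r, -clip), clip)
}

#' Cellwise LPR matrix
#'
#' LPR scores for every cell with `1 <= |i - j| <= h` and both bins
#' valid; all other cells (diagonal, beyond the horizon, invalid bins)
#' are exactly 0 and contribute nothing to any score.
#'
#' @param cm a `ContactMatrix`.
#' @param model a `DistanceMixtureModel`.
#' @param clip symmetric clipping bound (default 50).
#' @return symmetric n x n numeric matrix.
#' @export
lpr_matrix <- function(cm, model, clip = 50) {
  n <- n_bins(cm)
  out <- matrix(0, n, n)
  for (d in seq_len(min(model$h, n - 1L))) {
    i <- seq_len(n - d); j <- i + d
    keep <- cm$valid[i] & cm$valid[j]
    if (!any(keep)) next
    i <- i[keep]; j <- j[keep]
    v <- lpr(cm$counts[cbind(i, j)], d, model, clip = clip)
    out[cbind(i, j)] <- v
    out[cbind(j, i)] <- v
  }
  out
}

#' Classification log-likelihood of a segmentation under the mixture
#'
#' Sum over valid cells (1 <= d <= h) of
#' `log(P_d(class) * P_d(N | class))` where the class (intra/inter) is
#' taken from the segmentation. At fixed parameters this is, up to a
#' constant, an affine transform of the total domain score, which is
#' why alternating estimation and re-segmentation ascends it.
#'
#' @inheritParams estimate_mixture
#' @param model a `DistanceMixtureModel`.
#' @export
classification_loglik <- function(cm, seg, model) {
  cells <- .distance_cells(cm, seg, model$h, model$pseudocount)
  ll <- 0
  for (cl in cells) {
    p <- model$params[cl$d, ]
    x <- exp(cl$logx)
    la <- log(p$prior_intra) +
      stats::dlnorm(x, p$mu_intra, p$sigma_intra, log = TRUE)
    lb <- log(p$prior_inter) +
      stats::dlnorm(x, p$mu_inter, p$sigma_inter, log = TRUE)
    ll <- ll + sum(ifelse(cl$intra, la, lb))
  }
  ll
}
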