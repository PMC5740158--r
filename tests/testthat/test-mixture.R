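test_that("log-normal density matches closed form and normalizes", {
  expect_equal(lognormal_density(1, 0, 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # log(e) - 1 = 0, so P(e; mu=1, sd=1) = 1/(e * sqrt(2pi))
  expect_equal(lognormal_density(exp(1), 1, 1),
               exp(-1) / sqrt(2 * pi), tolerance = 1e-12)
  q <- integrate(function(x) lognormal_density(x, 0.3, 0.7), 0, Inf)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(lognormal_density(0, 0, 1), "x > 0")
  expect_error(lognormal_density(1, 0, 0), "sigma")
})

test_that("mixture estimation reproduces hand-computed mean/SD/priors", {
  # two domains [1,4], [5,8]; counts chosen so the d = 1 intra
  # log-counts (with pseudocount 1) are {0, 2, 1, 1, 1, 1}
  n <- 8
  m <- matrix(0, n, n)
  put <- function(i, j, v) m[cbind(c(i, j), c(j, i))] <<- exp(v) - 1
  put(1, 2, 0); put(2, 3, 2); put(3, 4, 1)
  put(5, 6, 1); put(6, 7, 1); put(7, 8, 1)
  put(4, 5, 0.5)                         # inter at d = 1 (one cell)
  put(1, 3, 1.5); put(2, 4, 0.5)         # intra d = 2
  put(5, 7, 1.2); put(6, 8, 0.8)
  put(3, 5, 0.2); put(4, 6, 0.8)         # inter d = 2
  cm <- contact_matrix(m, resolution = 1000L)
  seg <- segmentation(c(1, 5), c(4, 8), n, resolution = 1000L)
  model <- estimate_mixture(cm, seg, h = 2, pseudocount = 1,
                            min_samples = 2L)
  p1 <- model$params[1, ]
  expect_equal(p1$mu_intra, 1)                # mean of {0,2,1,1,1,1}
  expect_equal(p1$sigma_intra, sd(c(0, 2, 1, 1, 1, 1)))   # ddof = 1
  expect_equal(p1$prior_intra, 6 / 7)         # 6 intra, 1 inter cells
  p2 <- model$params[2, ]
  expect_equal(p2$mu_inter, 0.5)              # mean of {0.2, 0.8}
  expect_equal(p2$prior_intra + p2$prior_inter, 1)
  # d = 1 inter class has one cell -> mean/SD inherited from d = 2
  expect_equal(p1$sigma_inter, p2$sigma_inter)
  expect_equal(p1$mu_inter, p2$mu_inter)
})

test_that("degenerate single-domain annotation raises an error", {
  cm <- two_block_cm()
  seg1 <- segmentation(1, n_bins(cm), n_bins(cm), resolution = 40000L)
  expect_error(estimate_mixture(cm, seg1, h = 4), "degenerate")
})

test_that("posterior and LPR obey symmetry, prior and clipping rules", {
  par <- data.frame(d = 1:3, mu_intra = 1, sigma_intra = 0.5,
                    mu_inter = 1, sigma_inter = 0.5,
                    prior_intra = c(0.5, 0.7, 0.75),
                    prior_inter = c(0.5, 0.3, 0.25))
  model <- mixture_model(par)
  expect_equal(posterior_intra(c(0, 3, 100), 1, model), rep(0.5, 3))
  expect_equal(posterior_intra(5, 2, model), 0.7)
  expect_equal(lpr(17, 1, model), 0)
  expect_equal(lpr(17, 3, model), log(3), tolerance = 1e-12)
  # posterior normalization for distinct sub-models
  par2 <- transform(par, mu_intra = 2, sigma_inter = 0.9)
  m2 <- mixture_model(par2)
  for (N in c(0, 1, 10, 1000))
    expect_equal(posterior_intra(N, 1, m2) +
                   (1 - posterior_intra(N, 1, m2)), 1)
  # clipping keeps LPR finite over an extreme grid
  grid <- c(0, 1, 10, 1e2, 1e4, 1e6)
  v <- lpr(grid, 1, m2)
  expect_true(all(is.finite(v)) && all(abs(v) <= 50))
  # antisymmetry under swapping sub-models and priors
  par3 <- data.frame(d = 1, mu_intra = 2, sigma_intra = 0.4,
                     mu_inter = 0.5, sigma_inter = 0.8,
                     prior_intra = 0.6, prior_inter = 0.4)
  par3s <- data.frame(d = 1, mu_intra = 0.5, sigma_intra = 0.8,
                      mu_inter = 2, sigma_inter = 0.4,
                      prior_intra = 0.4, prior_inter = 0.6)
  for (N in c(0, 2, 7, 40))
    expect_equal(lpr(N, 1, mixture_model(par3)),
                 -lpr(N, 1, mixture_model(par3s)), tolerance = 1e-12)
})

test_that("LPR matrix is symmetric, horizon-limited and mask-aware", {
  cm <- two_block_cm(4, 4)
  cm$valid[3] <- FALSE
  seg <- segmentation(c(1, 5), c(4, 8), 8, resolution = 40000L)
  model <- estimate_mixture(cm, seg, h = 3, min_samples = 2L)
  L <- lpr_matrix(cm, model)
  expect_equal(L, t(L))
  expect_true(all(L[abs(row(L) - col(L)) > 3] == 0))
  expect_true(all(L[3, ] == 0) && all(L[, 3] == 0))
  expect_true(all(diag(L) == 0))
})

test_that("estimation recovers generating parameters within 3 SE", {
  # matrix simulated directly from a known theta_d with a known
  # segmentation; oracle = the generating parameters
  set.seed(101)
  n <- 700; h <- 5
  ends <- seq(20, n, by = 20)
  seg <- segmentation_from_boundaries(head(ends, -1), n,
                                      resolution = 40000L)
  ids <- domain_ids(seg)
  mu_i <- 3 - 0.2 * (1:h); s_i <- rep(0.5, h)
  mu_e <- 1.5 - 0.1 * (1:h); s_e <- rep(0.8, h)
  m <- matrix(0, n, n)
  for (d in 1:h) {
    i <- seq_len(n - d); j <- i + d
    intra <- ids[i] == ids[j]
    lx <- ifelse(intra, rnorm(length(i), mu_i[d], s_i[d]),
                 rnorm(length(i), mu_e[d], s_e[d]))
    m[cbind(i, j)] <- exp(lx)
    m[cbind(j, i)] <- exp(lx)
  }
  cm <- contact_matrix(m, resolution = 40000L)
  model <- estimate_mixture(cm, seg, h = h, pseudocount = 0)
  for (d in 1:h) {
    p <- model$params[d, ]
    n_i <- sum(ids[seq_len(n - d)] == ids[seq_len(n - d) + d])
    n_e <- (n - d) - n_i
    if (n_i >= 1000) {
      expect_lt(abs(p$mu_intra - mu_i[d]), 3 * s_i[d] / sqrt(n_i))
      expect_lt(abs(p$sigma_intra - s_i[d]),
                3 * s_i[d] / sqrt(2 * n_i))
    }
    if (n_e >= 1000) {
      expect_lt(abs(p$mu_inter - mu_e[d]), 3 * s_e[d] / sqrt(n_e))
      expect_lt(abs(p$sigma_inter - s_e[d]),
                3 * s_e[d] / sqrt(2 * n_e))
    }
    ptrue <- n_i / (n - d)
    expect_lt(abs(p$prior_intra - ptrue),
              3 * sqrt(ptrue * (1 - ptrue) / (n - d)) + 1e-12)
  }
})

test_that("mixture model TSV round-trips", {
  par <- data.frame(d = 1:4, mu_intra = c(2.1, 2.0, 1.9, 1.8),
                    sigma_intra = 0.5, mu_inter = 1.2,
                    sigma_inter = 0.81234567, prior_intra = 0.625,
                    prior_inter = 0.375)
  model <- mixture_model(par, pseudocount = 1)
  f <- withr::local_tempfile()
  write_mixture_tsv(model, f)
  m2 <- read_mixture_tsv(f)
  expect_equal(m2$params$sigma_inter, model$params$sigma_inter,
               tolerance = 1e-9)
  expect_equal(m2$pseudocount, 1)
  expect_equal(m2$h, 4)
})
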