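test_that("single power-law fit is exact on exact power laws", {
  d <- 1:20
  f <- fit_powerlaw(data.frame(d = d, mean = d^-1), pseudocount = 0,
                    resolution = 1)
  expect_equal(f$a, -1, tolerance = 1e-12)
  expect_equal(f$b, 0, tolerance = 1e-12)
  f2 <- fit_powerlaw(data.frame(d = d, mean = 5), pseudocount = 0,
                     resolution = 1)
  expect_equal(f2$a, 0, tolerance = 1e-12)
  expect_equal(f2$b, log(5), tolerance = 1e-12)
  f3 <- fit_powerlaw(data.frame(d = d, mean = 2 * d^-0.8),
                     pseudocount = 0, resolution = 1)
  expect_equal(f3$a, -0.8, tolerance = 1e-10)
  expect_equal(f3$b, log(2), tolerance = 1e-10)
})

test_that("bilinear fit recovers two-segment data and the breakpoint", {
  d <- 2:30
  y <- ifelse(d <= 8, -0.5 * log(d) + 3, -1.5 * log(d) + 3 + log(8))
  prof <- data.frame(d = d, mean = exp(y))
  fit <- fit_bilinear(prof, pseudocount = 0, resolution = 1)
  expect_false(fit$single)
  expect_equal(fit$breakpoint_d, 8)
  expect_equal(fit$a1, -0.5, tolerance = 1e-9)
  expect_equal(fit$a2, -1.5, tolerance = 1e-9)
  expect_equal(fit$b1, 3, tolerance = 1e-9)
  expect_equal(fit$sse, 0, tolerance = 1e-16)
  # independent grid-scan oracle over all admissible breakpoints
  sses <- vapply(2:(length(d) - 2), function(k) {
    f1 <- lm(y[1:k] ~ log(d[1:k]))
    f2 <- lm(y[(k + 1):length(d)] ~ log(d[(k + 1):length(d)]))
    sum(resid(f1)^2) + sum(resid(f2)^2)
  }, numeric(1))
  expect_equal(d[1 + which.min(sses)], 8)
})

test_that("bilinear nests the single line; ties pick smallest breakpoint", {
  d <- 1:12
  prof <- data.frame(d = d, mean = exp(-0.7 * log(d) + 2))
  fit <- fit_bilinear(prof, pseudocount = 0, resolution = 1)
  single <- fit_powerlaw(prof, pseudocount = 0, resolution = 1)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
  expect_equal(single$sse, 0, tolerance = 1e-18)
  expect_equal(fit$breakpoint_d, 2)      # smallest admissible breakpoint
  # nesting inequality on noisy profiles
  set.seed(21)
  for (rep in 1:10) {
    prof <- data.frame(d = 1:15,
                       mean = exp(-log(1:15) + rnorm(15, 0, 0.3)))
    bi <- fit_bilinear(prof, pseudocount = 0, resolution = 1)
    si <- fit_powerlaw(prof, pseudocount = 0, resolution = 1)
    expect_lte(bi$sse, si$sse + 1e-12)
  }
  # degenerate support falls back to a single segment
  small <- data.frame(d = 1:3, mean = c(9, 4, 2))
  expect_true(fit_bilinear(small, 0, 1)$single)
})

test_that("incremental breakpoint scan equals naive per-candidate refits", {
  set.seed(22)
  d <- sort(sample(2:60, 25))
  y <- -1.1 * log(d) + 4 + rnorm(25, 0, 0.4)
  prof <- data.frame(d = d, mean = exp(y))
  fit <- fit_bilinear(prof, pseudocount = 0, resolution = 1)
  naive <- vapply(2:(length(d) - 2), function(k) {
    f1 <- lm(y[1:k] ~ log(d[1:k]))
    f2 <- lm(y[(k + 1):length(d)] ~ log(d[(k + 1):length(d)]))
    sum(resid(f1)^2) + sum(resid(f2)^2)
  }, numeric(1))
  expect_equal(fit$sse, min(naive), tolerance = 1e-9)
  expect_equal(fit$breakpoint_d, d[1 + which.min(naive)])
})

test_that("background regions partition the owned cells", {
  spec <- default_sim_spec()
  sim <- simulate_matrix(spec, seed = 31)
  cm <- sim$matrix
  seg <- segmentation(sim$truth$tads[, 1], sim$truth$tads[, 2],
                      n_bins(cm), resolution = cm$resolution)
  h <- 125L
  forest <- build_hierarchy(cm, seg, max_merge_bins = 125L, h = h)
  bg <- build_background(cm, forest, h = h)
  n <- n_bins(cm)
  dmat <- abs(col(bg$owner) - row(bg$owner))
  inside <- dmat >= 1 & dmat <= h &
    outer(cm$valid, cm$valid, "&")
  expect_true(all(!is.na(bg$owner[inside])))   # every such cell owned
  expect_true(all(is.na(bg$owner[!inside])))
  # leaf cells owned by their leaf
  ids <- domain_ids(seg)
  same <- outer(ids, ids, "==") & inside
  expect_true(all(bg$owner[same] ==
                  rep(ids, n)[same]))
})

test_that("expected matrix inverts the fits; residuals behave", {
  # constant fit a = 0, b = log 5, pseudocount 1 -> expected 4
  n <- 12
  m <- matrix(4, n, n); diag(m) <- 0
  cm <- contact_matrix(m, resolution = 1000L)
  seg <- segmentation(1, n, n, resolution = 1000L)
  bg <- build_background(cm, forest_from_segmentation(seg), h = n - 1,
                         pseudocount = 1)
  ex <- expected_matrix(bg)
  off <- abs(col(ex) - row(ex)) >= 1
  expect_equal(ex[off], rep(4, sum(off)), tolerance = 1e-9)
  expect_equal(ex, t(ex))
  expect_true(all(ex[off] >= 0))
  r <- residual_map(cm, ex, 1)
  expect_equal(r[off], rep(0, sum(off)), tolerance = 1e-9)
  expect_true(all(is.na(diag(r))))
  # doubling one cell above expectation moves only that residual
  m2 <- m; m2[2, 7] <- m2[7, 2] <- 9   # (9+1)/(4+1) = 2
  cm2 <- contact_matrix(m2, resolution = 1000L)
  r2 <- residual_map(cm2, ex, 1)
  expect_equal(r2[2, 7], log(2), tolerance = 1e-9)
  expect_equal(r2[3, 8], 0, tolerance = 1e-9)
  # RMSE of a constant offset is that offset
  expect_equal(fit_rmse(r2 * 0 + log(2)), log(2), tolerance = 1e-12)
  expect_equal(fit_rmse(r), 0, tolerance = 1e-9)
})

test_that("a single all-covering domain yields one fit and no Sky", {
  n <- 10
  m <- matrix(2, n, n); diag(m) <- 0
  cm <- contact_matrix(m)
  seg <- segmentation(1, n, n)
  bg <- build_background(cm, forest_from_segmentation(seg), h = n - 1)
  expect_length(bg$fits, 2L)           # domain + Sky slot
  expect_null(bg$fits[["0"]])          # Sky has empty support
})

test_that("per-domain slopes are recovered from simulated decay", {
  spec <- simulation_spec(
    n_bins = 120L, tads = rbind(c(1, 40), c(41, 80), c(81, 120)),
    tad_params = list(
      list(a1 = -0.7, b1 = log(150) + 0.7 * log(40000), a2 = NA,
           b2 = NA, breakpoint_d = NA),
      list(a1 = -1.0, b1 = log(120) + 1.0 * log(40000), a2 = NA,
           b2 = NA, breakpoint_d = NA),
      list(a1 = -1.3, b1 = log(100) + 1.3 * log(40000), a2 = NA,
           b2 = NA, breakpoint_d = NA)),
    sky = list(slope = -1.5, I1 = 20))
  sim <- simulate_matrix(spec, seed = 33)
  seg <- segmentation(c(1, 41, 81), c(40, 80, 120), 120,
                      resolution = 40000L)
  bg <- build_background(sim$matrix, forest_from_segmentation(seg),
                         h = 119L, bilinear = FALSE)
  slopes <- vapply(as.character(1:3), function(k) bg$fits[[k]]$a1,
                   numeric(1))
  expect_equal(unname(slopes), c(-0.7, -1.0, -1.3), tolerance = 0.12)
})

test_that("refitting a resampled background reproduces its expectation", {
  spec <- simulation_spec(n_bins = 100L,
                          tads = rbind(c(1, 30), c(31, 70), c(71, 100)))
  sim <- simulate_matrix(spec, seed = 41)
  seg <- segmentation(c(1, 31, 71), c(30, 70, 100), 100,
                      resolution = 40000L)
  forest <- forest_from_segmentation(seg)
  bg <- build_background(sim$matrix, forest, h = 99L)
  cm2 <- simulate_from_background(bg, seed = 42)
  bg2 <- build_background(cm2, forest, h = 99L)
  e1 <- expected_matrix(bg); e2 <- expected_matrix(bg2)
  keep <- !is.na(e1) & !is.na(e2) & e1 > 5
  expect_lt(median(abs(log(e2[keep] + 1) - log(e1[keep] + 1))), 0.1)
})
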