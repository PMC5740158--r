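test_that("noise-free simulation equals the analytic mean matrix", {
  spec <- simulation_spec(n_bins = 40L, tads = rbind(c(1, 20),
                                                     c(21, 40)),
                          noise = "none")
  sim <- simulate_matrix(spec, seed = 1)
  expect_equal(sim$matrix$counts, sim$truth$mean_matrix)
  expect_equal(sim$matrix$counts, t(sim$matrix$counts))
  # domain cells follow the domain curve, distal cells the Sky curve
  p1 <- sim$truth$tad_params[[1]]
  expect_equal(sim$matrix$counts[1, 2],
               hicdomains:::.curve_mean(p1, 1, 40000L))
  expect_equal(sim$matrix$counts[1, 40],
               hicdomains:::.curve_mean(sim$truth$sky, 39, 40000L))
})

test_that("simulation is seed-deterministic and seeds differ", {
  spec <- default_sim_spec()
  a <- simulate_matrix(spec, seed = 5)
  b <- simulate_matrix(spec, seed = 5)
  c <- simulate_matrix(spec, seed = 6)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth$tads, b$truth$tads)
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("Poisson resampling matches the generating means", {
  spec <- simulation_spec(n_bins = 20L, tads = rbind(c(1, 10),
                                                     c(11, 20)),
                          noise = "poisson")
  mu <- simulate_matrix(
    simulation_spec(n_bins = 20L, tads = rbind(c(1, 10), c(11, 20)),
                    tad_params = simulate_matrix(spec, 1)$truth$tad_params,
                    noise = "none"), seed = 1)$truth$mean_matrix
  spec2 <- simulation_spec(n_bins = 20L,
                           tads = rbind(c(1, 10), c(11, 20)),
                           tad_params = simulate_matrix(spec,
                                                        1)$truth$tad_params,
                           noise = "poisson")
  reps <- 400
  acc <- 0
  for (r in seq_len(reps))
    acc <- acc + simulate_matrix(spec2, seed = 1000 + r)$matrix$counts
  emp <- acc / reps
  cell <- c(2, 5)   # intra-domain cell, mean > 10
  se <- sqrt(mu[cell[1], cell[2]] / reps)
  expect_lt(abs(emp[cell[1], cell[2]] - mu[cell[1], cell[2]]), 3 * se)
  cell2 <- c(3, 17) # inter-domain (Sky) cell
  se2 <- sqrt(max(mu[cell2[1], cell2[2]], 1e-9) / reps)
  expect_lt(abs(emp[cell2[1], cell2[2]] - mu[cell2[1], cell2[2]]),
            3 * se2 + 1e-9)
})

test_that("planted enrichment folds multiply the mean cells", {
  enr <- data.frame(i = c(3, 8), j = c(9, 15), fold = c(8, 2))
  spec <- simulation_spec(n_bins = 20L, tads = rbind(c(1, 10),
                                                     c(11, 20)),
                          enrich = enr, noise = "none")
  spec0 <- simulation_spec(n_bins = 20L, tads = rbind(c(1, 10),
                                                      c(11, 20)),
                           noise = "none")
  m1 <- simulate_matrix(spec, seed = 2)
  m0 <- simulate_matrix(
    simulation_spec(n_bins = 20L, tads = rbind(c(1, 10), c(11, 20)),
                    tad_params = m1$truth$tad_params, noise = "none"),
    seed = 2)
  expect_equal(m1$matrix$counts[3, 9], 8 * m0$matrix$counts[3, 9])
  expect_equal(m1$matrix$counts[9, 3], m1$matrix$counts[3, 9])
  expect_equal(m1$matrix$counts[8, 15], 2 * m0$matrix$counts[8, 15])
  expect_equal(m1$matrix$counts[4, 9], m0$matrix$counts[4, 9])
  expect_error(simulation_spec(n_bins = 20L,
                               enrich = data.frame(i = 1, j = 5,
                                                   fold = 0.5)),
               "fold")
})

test_that("merge rectangles blend domain and Sky profiles at alpha", {
  spec <- simulation_spec(
    n_bins = 30L, tads = rbind(c(1, 15), c(16, 30)),
    merges = list(list(children = c(1, 2), alpha = 0.3)),
    noise = "none")
  sim <- simulate_matrix(spec, seed = 4)
  cm <- sim$matrix
  # recompute alpha from the generated matrix
  I_m <- rect_profile(cm, c(1, 15), c(16, 30), h = 29L)
  I_t <- hicdomains:::.stats_to_profile(hicdomains:::.pool_stats(
    hicdomains:::.triangle_stats(cm, 1, 15, 29L),
    hicdomains:::.triangle_stats(cm, 16, 30, 29L)))
  I_s <- data.frame(d = 1:29,
                    mean = hicdomains:::.curve_mean(sim$truth$sky,
                                                    1:29, 40000L))
  a <- merge_alpha(I_m, I_t, I_s)
  expect_equal(a$alpha, 0.3, tolerance = 1e-10)
})

test_that("masked bins stay invalid through background resampling", {
  spec <- simulation_spec(n_bins = 40L, tads = rbind(c(1, 20),
                                                     c(21, 40)),
                          mask_bins = c(7L, 8L))
  sim <- simulate_matrix(spec, seed = 11)
  expect_false(any(sim$matrix$valid[7:8]))
  expect_true(all(sim$matrix$counts[7, ] == 0))
  seg <- segmentation(c(1, 21), c(20, 40), 40, resolution = 40000L)
  bg <- build_background(sim$matrix, forest_from_segmentation(seg),
                         h = 39L)
  cm2 <- simulate_from_background(bg, seed = 12)
  expect_false(any(cm2$valid[7:8]))
  expect_true(all(cm2$counts[7:8, ] == 0))
})

test_that("refit error decreases with read depth", {
  base <- simulation_spec(n_bins = 80L, tads = rbind(c(1, 40),
                                                     c(41, 80)))
  par <- simulate_matrix(base, 1)$truth$tad_params
  seg <- segmentation(c(1, 41), c(40, 80), 80, resolution = 40000L)
  ids <- domain_ids(seg)
  # evaluate on well-covered cells (intra-domain, d <= 10) where the
  # Poisson noise, not the pseudocount, dominates the log residuals
  cells <- which(outer(ids, ids, "==") &
                 abs(col(diag(80)) - row(diag(80))) %in% 1:10 &
                 upper.tri(diag(80)), arr.ind = TRUE)
  err <- vapply(c(1, 8, 64), function(depth) {
    spec <- simulation_spec(n_bins = 80L,
                            tads = rbind(c(1, 40), c(41, 80)),
                            tad_params = par, depth = depth)
    sim <- simulate_matrix(spec, seed = 21)
    bg <- build_background(sim$matrix, forest_from_segmentation(seg),
                           h = 79L)
    r <- residual_map(sim$matrix, expected_matrix(bg), 1)
    fit_rmse(r, cells)
  }, numeric(1))
  expect_gt(err[1], err[2])
  expect_gt(err[2], err[3])
  expect_true(all(err > 0))
})

test_that("YAML spec round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_bins: 30", "resolution: 20000",
               "tads:", "- [1, 12]", "- [13, 30]",
               "sky: {slope: -1.2, I1: 12.0}", "noise: none"), f)
  spec <- read_sim_spec(f)
  expect_s3_class(spec, "SimulationSpec")
  expect_equal(spec$n_bins, 30L)
  expect_equal(spec$tads[2, ], c(13L, 30L))
  sim <- simulate_matrix(spec, seed = 1)
  expect_equal(n_bins(sim$matrix), 30L)
  expect_equal(sim$matrix$resolution, 20000L)
})
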