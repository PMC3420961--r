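test_that("band filter passes in-band tones and rejects out-of-band content", {
  fs <- 500; n <- 4000
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  core <- 500:3500  # avoid filter edge transients
  y <- band_filter(x, c(8, 10), fs)
  expect_equal(stats::sd(y[core]) / stats::sd(x[core]), 1, tolerance = 0.05)
  z <- band_filter(x, c(30, 45), fs)
  expect_lt(sqrt(mean(z[core]^2)) / sqrt(mean(x[core]^2)), 0.01)
  # zero-phase: filtering the reversed signal and reversing equals filtering
  xr <- rev(band_filter(rev(x), c(8, 10), fs))
  deep <- 1200:2800  # away from both ends, where finite-length transients live
  expect_equal(y[deep], xr[deep], tolerance = 1e-3)
  expect_error(band_filter(x, c(10, 8), fs), "inverted")
  expect_error(band_filter(x, c(10, 400), fs), "Nyquist")
})

test_that("SL parameter auto-tuning follows the band-based recipe", {
  p <- sl_params(500, band = c(8, 10))
  expect_equal(p$lag, round(500 / 30))
  expect_equal(p$embed_dim, round(3 * 10 / 8) + 1)
  expect_equal(p$w1, 2 * p$lag * (p$embed_dim - 1))
  expect_equal(p$w2, p$w1 + 1000)
  # broadband demand is capped
  pb <- sl_params(500, band = c(0.5, 45))
  expect_lte(pb$embed_dim, 10)
  expect_error(sl_params(500, band = c(8, 10), p_ref = 0.9), "p_ref")
  expect_error(sl_params(500), "band")
})

test_that("SL is 1 for identical signals, symmetric, and near p_ref for noise", {
  fs <- 500
  prm <- sl_params(fs, band = c(8, 10), w2 = 400, ref_step = 4)
  n <- 1200
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 9 * t) + 0.3 * addnet:::.with_seed(1, stats::rnorm(n))
  expect_equal(sl_pairwise(x, x, prm), 1)
  y <- sin(2 * pi * 9 * t + 1) + 0.3 * addnet:::.with_seed(2, stats::rnorm(n))
  expect_identical(sl_pairwise(x, y, prm), sl_pairwise(y, x, prm))

  sls <- vapply(1:20, function(s) {
    a <- addnet:::.with_seed(300 + s, stats::rnorm(n))
    b <- addnet:::.with_seed(600 + s, stats::rnorm(n))
    sl_pairwise(a, b, prm)
  }, numeric(1))
  se <- stats::sd(sls) / sqrt(length(sls))
  expect_lt(abs(mean(sls) - prm$p_ref), 3 * se + 0.002)
  expect_true(all(sls >= 0 & sls <= 1))
  expect_error(sl_pairwise(x[1:100], y[1:100], prm), "too short")
  expect_error(sl_pairwise(rep(1, n), y, prm), "constant")
})

test_that("functional network matches pairwise SL and flags its floor", {
  fs <- 500; n <- 1400
  t <- (0:(n - 1)) / fs
  prm <- sl_params(fs, band = c(8, 10), w2 = 400, ref_step = 4)
  base <- sin(2 * pi * 9 * t)
  tr <- cbind(base, base, base)
  fn <- functional_network(tr, band = NULL, params = prm,
                           labels = c("a", "b", "c"))
  off <- fn$sl_matrix[upper.tri(fn$sl_matrix)]
  expect_true(all(off > 0.99))
  expect_equal(diag(fn$sl_matrix), stats::setNames(rep(0, 3), c("a", "b", "c")))

  # consistency with the pairwise estimator
  x <- base + 0.5 * addnet:::.with_seed(4, stats::rnorm(n))
  y <- base + 0.5 * addnet:::.with_seed(5, stats::rnorm(n))
  z <- addnet:::.with_seed(6, stats::rnorm(n))
  tr2 <- cbind(x, y, z)
  fn2 <- functional_network(tr2, band = NULL, params = prm)
  expect_equal(fn2$sl_matrix[1, 2], sl_pairwise(x, y, prm), tolerance = 1e-12)
  expect_equal(fn2$sl_matrix[1, 3], sl_pairwise(x, z, prm), tolerance = 1e-12)
  expect_equal(unname(fn2$functional_degree), unname(rowSums(fn2$sl_matrix)))

  # independent noise: functional degree near (N-1) * p_ref
  noise_tr <- vapply(1:6, function(s) addnet:::.with_seed(900 + s, stats::rnorm(n)),
                     numeric(n))
  fn3 <- functional_network(noise_tr, band = NULL, params = prm)
  expect_equal(mean(fn3$functional_degree), 5 * prm$p_ref, tolerance = 0.6 * 5 * prm$p_ref)
  expect_error(functional_network(noise_tr[, 1, drop = FALSE], band = NULL,
                                  params = prm), "2 regions")
})

test_that("SL between two coupled masses increases with coupling strength", {
  p <- nmm_params()
  prm <- sl_params(p$sample_rate, band = c(8, 13), w2 = 500, ref_step = 4)
  svals <- c(0, 1, 1.5, 2)
  sls <- matrix(0, 3, length(svals))
  for (seed in 1:3) {
    sls[seed, ] <- vapply(svals, function(S) {
      net <- two_node_network(S)
      rec <- simulate_network(net, p, simulation_config(
        epoch_samples = 2048, warmup_samples = 500, seed = seed))
      ve <- rec$ve[[1]]
      x <- band_filter(ve[, 1], c(8, 13), p$sample_rate)
      y <- band_filter(ve[, 2], c(8, 13), p$sample_rate)
      sl_pairwise(x, y, prm)
    }, numeric(1))
  }
  # monotone in the coupling on seed-averaged estimates
  expect_equal(stats::cor(colMeans(sls), svals, method = "spearman"), 1)
})
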