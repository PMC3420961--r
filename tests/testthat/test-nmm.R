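test_that("sigmoid hits its midpoint, saturates, and is monotone", {
  for (trip in list(c(max_rate = 1000, threshold = 6, steepness = 0.9),
                    c(max_rate = 5, threshold = -2, steepness = 0.25))) {
    expect_equal(nmm_sigmoid(trip[["threshold"]], trip), trip[["max_rate"]] / 2)
    expect_equal(nmm_sigmoid(-1e6, trip), 0, tolerance = 1e-12)
    expect_equal(nmm_sigmoid(1e6, trip), trip[["max_rate"]], tolerance = 1e-12)
    v <- sort(stats::rnorm(50, trip[["threshold"]], 5))
    expect_true(all(diff(nmm_sigmoid(v, trip)) >= 0))
  }
  expect_error(nmm_sigmoid(NaN, c(1000, 6, 0.9)), "non-finite")
})

test_that("impulse response is causal with the closed-form maximum and integral", {
  gain <- 1.6; rise <- 605; decay <- 55
  expect_equal(impulse_response(0, gain, rise, decay), 0)
  tt <- seq(1e-4, 0.2, by = 1e-5)
  h <- impulse_response(tt, gain, rise, decay)
  expect_true(all(h > 0))
  t_star <- log(rise / decay) / (rise - decay)
  expect_equal(tt[which.max(h)], t_star, tolerance = 1e-3)
  quad <- stats::integrate(impulse_response, 0, Inf, gain = gain,
                           rise = rise, decay = decay)$value
  expect_equal(quad, gain * (1 / decay - 1 / rise), tolerance = 1e-8)
  expect_error(impulse_response(0.01, gain, 55, 55), "differ")
  expect_error(impulse_response(-0.1, gain, rise, decay), "non-negative")
})

test_that("recursive filter update equals direct convolution with its discrete kernel", {
  p <- nmm_params(thalamic_mean = 0, thalamic_sd = 0)
  dt <- 1 / p$sample_rate
  n <- p$sample_rate  # 1 s
  u <- addnet:::.with_seed(11, stats::rnorm(n, sd = 100))
  st <- nmm_state(1, p)
  # isolate the input filter: no intra-mass feedback
  ve <- numeric(n)
  for (t in seq_len(n)) {
    st <- step_mass(st, p, external_input = u[t], noise_draw = 0,
                    c1 = 0, c2 = 0, pt = 0)
    ve[t] <- st$ve
  }
  d1 <- exp(-p$he_decay * dt); k1 <- (1 - d1) / p$he_decay
  d2 <- exp(-p$he_rise * dt); k2 <- (1 - d2) / p$he_rise
  j <- 0:(n - 1)
  g <- p$he_gain * (k1 * d1^j - k2 * d2^j)
  ve_conv <- vapply(seq_len(n), function(t) sum(g[1:t] * u[t:1]), numeric(1))
  expect_equal(ve, ve_conv, tolerance = 1e-6)
})

test_that("a mass initialized at its quiescent fixed point stays there", {
  p <- nmm_params(thalamic_mean = 0, thalamic_sd = 0)
  fp <- nmm_rest_state(p)
  st <- fp$state
  e0 <- st$e_rate; i0 <- st$i_rate
  for (t in 1:200) st <- step_mass(st, p, external_input = 0, noise_draw = 0)
  expect_equal(st$e_rate, e0, tolerance = 1e-9)
  expect_equal(st$i_rate, i0, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical single-mass traces", {
  p <- nmm_params()
  a <- simulate_mass(p, 400, seed = 5, warmup_samples = 100)
  b <- simulate_mass(p, 400, seed = 5, warmup_samples = 100)
  expect_identical(a, b)
  c <- simulate_mass(p, 400, seed = 6, warmup_samples = 100)
  expect_false(identical(a$ve, c$ve))
})

test_that("an uncoupled mass with default parameters oscillates in the alpha band", {
  p <- nmm_params()
  peaks <- vapply(1:5, function(s) {
    tr <- simulate_mass(p, 4096, seed = s)
    alpha_peak(power_spectrum(tr$ve, p$sample_rate))
  }, numeric(1))
  expect_true(all(peaks >= 8 & peaks <= 13))
})

test_that("rates stay bounded and potentials finite over a long run", {
  p <- nmm_params()
  noise <- addnet:::region_noise_stream(9, 1, 1e5)
  res <- addnet:::.run_epochs(p, matrix(0, 1, 1), c1 = p$c1, c2 = p$c2,
                              pt = p$pt, noise = noise, n_record = 1e5)
  expect_true(all(is.finite(res$ve)))
  expect_true(all(res$e_rate >= 0))
  expect_true(all(res$e_rate <= p$sigmoid_e[["max_rate"]]))
})

test_that("invalid parameters and diverged states are rejected", {
  expect_error(nmm_params(he_decay = 55, he_rise = 55), "degenerate")
  expect_error(nmm_params(sample_rate = 100), "140")
  expect_error(nmm_params(sigmoid_e = c(max_rate = -1, threshold = 0, steepness = 1)),
               "positive")
  p <- nmm_params()
  st <- nmm_state(1, p)
  st$ve <- NaN
  expect_error(step_mass(st, p), "diverged")
})
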