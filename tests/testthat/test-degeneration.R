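test_that("loss factor satisfies its contract in both forms", {
  expect_equal(compute_loss(0, 1e-4), 1)
  ma <- seq(0, 2000, by = 50)
  l <- compute_loss(ma, 1e-4)
  expect_true(all(l > 0 & l <= 1))
  expect_true(all(diff(l) < 0))
  # decreasing in the rate at fixed positive activity
  expect_gt(compute_loss(400, 1e-4), compute_loss(400, 2e-4))
  # linear form
  ll <- compute_loss(ma, 1e-4, form = "linear")
  expect_true(all(ll >= 0 & ll <= 1))
  expect_equal(compute_loss(0, 1e-4, form = "linear"), 1)
  expect_error(compute_loss(-1, 1e-4), "non-negative")
  expect_error(compute_loss(10, 0), "loss_rate")
})

test_that("activity-dependent updates compound multiplicatively per region", {
  p <- nmm_params()
  net <- structural_network(matrix(0, 1, 1))
  deg <- degeneration_state(net, p, loss_rate = 1e-3)
  c10 <- deg$c1
  deg <- apply_add(deg, max_act = 500)
  deg <- apply_add(deg, max_act = 500)
  expect_equal(deg$c1, c10 * exp(-1e-3 * 500)^2)
  expect_equal(deg$update, 2L)

  # silence leaves everything untouched
  net2 <- two_node_network(1.5, gain = 1)
  d2 <- degeneration_state(net2, p, loss_rate = 1e-3)
  d2b <- apply_add(d2, max_act = c(0, 0))
  expect_equal(d2b$c1, d2$c1)
  expect_equal(d2b$coupling, d2$coupling)

  # edge (i, j) shrinks by loss_i * loss_j, staying symmetric
  d2c <- apply_add(d2, max_act = c(100, 300))
  l <- compute_loss(c(100, 300), 1e-3)
  expect_equal(d2c$coupling[1, 2], 1.5 * l[1] * l[2])
  expect_equal(d2c$coupling, t(d2c$coupling))
  expect_equal(d2c$c2[2], p$c2 * l[2])
  expect_equal(d2c$pt[1], p$pt * l[1])
})

test_that("the activity buffer requires 20 filled steps", {
  m <- matrix(1, 19, 3)
  expect_error(max_activity(m), "buffer not filled")
  m2 <- rbind(matrix(1, 30, 3))
  m2[30, 2] <- 7
  expect_equal(max_activity(m2), c(1, 7, 1))
})

test_that("random degeneration is spatially uniform", {
  p <- nmm_params()
  net <- toy_network(n = 5, seed = 4)
  deg <- degeneration_state(net, p, loss_rate = 1e-3)
  for (u in 1:4) {
    deg <- apply_rd(deg, reference_loss = 0.93)
    s <- normalized_node_strength(deg)
    expect_equal(unname(s), rep(0.93^(2 * u), 5), tolerance = 1e-12)
    expect_equal(stats::var(s), 0)
  }
  # reference 1 is a no-op
  d0 <- degeneration_state(net, p, loss_rate = 1e-3)
  d1 <- apply_rd(d0, reference_loss = 1)
  expect_equal(d1$coupling, d0$coupling)
  expect_error(apply_rd(d0, reference_loss = 0), "0, 1")
  expect_error(apply_rd(d0, reference_loss = 1.2), "0, 1")
  # identical activity everywhere: ADD and derived RD coincide
  da <- apply_add(degeneration_state(net, p, loss_rate = 1e-3), rep(250, 5))
  dr <- apply_rd(degeneration_state(net, p, loss_rate = 1e-3), max_act = rep(250, 5))
  expect_equal(da$coupling, dr$coupling)
  expect_equal(da$c1, dr$c1)
})

test_that("normalized node strength is 1 at baseline and tracks damage", {
  p <- nmm_params()
  net <- toy_network(n = 5, seed = 4)
  deg <- degeneration_state(net, p)
  expect_equal(unname(normalized_node_strength(deg)), rep(1, 5))
  # halving all incident couplings of one node halves its ratio
  loss <- c(0.5, 1, 1, 1, 1)
  deg$coupling <- deg$coupling * outer(loss, loss)
  expect_equal(unname(normalized_node_strength(deg))[1], 0.5)
})

test_that("degeneration trajectories are monotone and reproducible", {
  p <- nmm_params()
  net <- toy_network(n = 4, seed = 2)
  rec <- run_degeneration(net, p, mode = "add", n_updates = 4,
                          epoch_samples = 256, warmup_samples = 128,
                          seed = 3, loss_rate = 1e-4)
  tr <- rec$trajectory
  expect_equal(tr$normalized_node_strength[tr$update == 0], rep(1, 4))
  for (reg in unique(tr$region)) {
    nns <- tr$normalized_node_strength[tr$region == reg]
    expect_true(all(diff(nns) <= 1e-12))
  }
  rec2 <- run_degeneration(net, p, mode = "add", n_updates = 4,
                           epoch_samples = 256, warmup_samples = 128,
                           seed = 3, loss_rate = 1e-4)
  expect_identical(rec$trajectory, rec2$trajectory)
  # RD: zero between-region variance at every update
  rrd <- run_degeneration(net, p, mode = "rd", n_updates = 4,
                          epoch_samples = 256, warmup_samples = 128,
                          seed = 3, loss_rate = 1e-4)
  v <- tapply(rrd$trajectory$normalized_node_strength, rrd$trajectory$update, stats::var)
  expect_true(all(v < 1e-24))
})
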