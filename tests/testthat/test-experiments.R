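test_that("pearson matches the textbook product-moment formula", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  a <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  b <- c(2.0, 3.1, 2.5, 6.0, 3.9)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), manual, tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:3, 1:4), "length")
})

test_that("hub contrast reproduces the Welch statistic on a hand-built toy", {
  k <- stats::setNames(c(9, 9, 8, 8, 3, 3, 2, 2, 1, 1, 1, 1), letters[1:12])
  part <- classify_hubs(k, n_bins = 6)
  expect_length(part$hubs, 2)
  vals <- stats::setNames(c(10, 12, 5, 6, 5, 4, 6, 5, 4, 6, 5, 5), letters[1:12])
  hc <- hub_contrast(vals, part, alternative = "greater")
  hv <- vals[part$hubs]; nv <- vals[part$non_hubs]
  tstat <- (mean(hv) - mean(nv)) /
    sqrt(stats::var(hv) / length(hv) + stats::var(nv) / length(nv))
  expect_equal(hc$statistic, tstat, tolerance = 1e-12)
  expect_lt(hc$p_value, 0.05)
  # identical groups: no difference, p about 1
  same <- stats::setNames(rep(5, 12), letters[1:12])
  hc0 <- hub_contrast(same, part)
  expect_equal(hc0$difference, 0)
  expect_equal(hc0$p_value, 1)
})

test_that("binned summaries are internally consistent with the per-region table", {
  k <- cortical_degrees()
  part <- classify_hubs(k)
  vals <- stats::setNames(as.numeric(k) * 2 + 1, names(k))
  bs <- binned_summary(vals, part)
  expect_equal(nrow(bs), 6)
  expect_equal(sum(bs$n), 78)
  for (b in 1:6)
    expect_equal(bs$mean[b], mean(vals[part$bins[[b]]]))
  expect_true(all(diff(bs$mean_degree) >= 0))
})

test_that("experiment drivers return coherent, reproducible reports", {
  p <- nmm_params()
  net <- generate_degree_matched(c(4L, 3L, 3L, 2L, 2L, 2L, 2L, 1L, 2L, 3L, 2L, 2L),
                                 seed = 2)
  rep1 <- experiment1(net, S_values = c(0, 1.5), n_runs = 2, seed = 5,
                      params = p, epoch_samples = 512, warmup_samples = 256)
  expect_s3_class(rep1, "experiment1_report")
  expect_equal(nrow(rep1$per_region[["S=1.5"]]), 12)
  expect_true(all(c("total_power", "spike_density", "alpha_peak_hz") %in%
                    rep1$correlations$metric))
  rep1b <- experiment1(net, S_values = c(0, 1.5), n_runs = 2, seed = 5,
                       params = p, epoch_samples = 512, warmup_samples = 256)
  expect_identical(rep1$correlations, rep1b$correlations)
  # binned means recompute exactly from the per-region table
  tab <- rep1$per_region[["S=1.5"]]
  vals <- stats::setNames(tab$total_power, tab$region)
  expect_equal(rep1$binned[["S=1.5"]]$total_power$mean,
               binned_summary(vals, rep1$partition)$mean)
})

test_that("random degeneration shows no hub/non-hub separation in experiment 2", {
  p <- nmm_params()
  net <- generate_degree_matched(c(4L, 3L, 3L, 2L, 2L, 2L, 2L, 1L, 2L, 3L, 2L, 2L),
                                 seed = 2)
  rep2 <- experiment2(net, mode = "rd", n_updates = 3, S = 1.5, n_runs = 1,
                      seed = 4, params = p, epoch_samples = 256,
                      loss_rate = 1e-4, metric_updates = integer(0))
  expect_s3_class(rep2, "experiment2_report")
  tc <- rep2$timecourse
  for (u in unique(tc$update)) {
    hub_v <- tc$normalized_node_strength[tc$update == u & tc$group == "hub"]
    non_v <- tc$normalized_node_strength[tc$update == u & tc$group == "non_hub"]
    expect_equal(hub_v, non_v, tolerance = 1e-12)
  }
  expect_true(all(abs(rep2$contrasts$difference) < 1e-12))
})
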