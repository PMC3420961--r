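test_that("degree thresholding keeps the exact edge budget deterministically", {
  n <- 78
  w <- addnet:::.with_seed(10, {
    m <- matrix(stats::runif(n * n), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  g <- threshold_to_degree(w, 8)
  expect_equal(igraph::ecount(g), 312)
  expect_equal(mean(igraph::degree(g)), 8)
  # all-equal weights: deterministic lexicographic tie-break
  we <- matrix(1, 10, 10); diag(we) <- 0
  g1 <- threshold_to_degree(we, 4)
  g2 <- threshold_to_degree(we, 4)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  # monotone: a higher target keeps a superset of edges
  g8 <- threshold_to_degree(w, 8); g12 <- threshold_to_degree(w, 12)
  e8 <- apply(igraph::as_edgelist(g8), 1, paste, collapse = "-")
  e12 <- apply(igraph::as_edgelist(g12), 1, paste, collapse = "-")
  expect_true(all(e8 %in% e12))
  # degenerate: too few nonzero weights
  sparse <- matrix(0, 10, 10); sparse[1, 2] <- sparse[2, 1] <- 1
  expect_error(threshold_to_degree(sparse, 4), "nonzero")
  expect_warning(gs <- threshold_to_degree(sparse, 4, on_short = "warn"), "nonzero")
  expect_equal(igraph::ecount(gs), 1)
  expect_error(threshold_to_degree(w, 78), "too high")
})

test_that("clustering and path length match hand-enumerated toy graphs", {
  k5 <- igraph::make_full_graph(5)
  m <- clustering_and_path(k5)
  expect_equal(m$cp, 1)
  expect_equal(m$lp, 1)

  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  m2 <- clustering_and_path(p4)
  expect_equal(m2$cp, 0)
  expect_equal(m2$lp, (1 * 3 + 2 * 2 + 3 * 1) / 6)  # all 6 pairs enumerated

  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3), igraph::make_full_graph(3))
  m3 <- clustering_and_path(tri2)
  expect_equal(m3$cp, 1)
  expect_equal(m3$lp, 1)  # within-component pairs only
  expect_equal(m3$disconnected_fraction, 9 / 15)
  expect_error(clustering_and_path(igraph::make_empty_graph(0)), "empty")
})

test_that("small-world indices are near 1 for randomized graphs and large for lattices", {
  g <- addnet:::.with_seed(5, igraph::sample_gnp(78, 0.12))
  sw <- normalized_small_world(g, n_surrogates = 15, seed = 2)
  expect_lt(abs(sw$gamma - 1), 2 * sw$cp_rand_sd / sw$cp_rand_mean + 0.2)
  expect_lt(abs(sw$lambda - 1), 0.1)

  ring <- igraph::sample_smallworld(1, 78, 4, 0)  # ring lattice, k = 8
  sw2 <- normalized_small_world(ring, n_surrogates = 10, seed = 3)
  expect_gt(sw2$gamma, 2)
  expect_gt(sw2$lambda, 1)
  # reproducible per seed
  sw3 <- normalized_small_world(ring, n_surrogates = 10, seed = 3)
  expect_identical(sw2$gamma, sw3$gamma)
})

test_that("newman modularity matches igraph on arbitrary partitions", {
  for (s in 1:5) {
    g <- addnet:::.with_seed(s, igraph::sample_gnp(20, 0.2))
    if (igraph::ecount(g) == 0) next
    mem <- addnet:::.with_seed(100 + s, sample(1:4, 20, replace = TRUE))
    expect_equal(newman_modularity(g, mem),
                 igraph::modularity(g, mem), tolerance = 1e-12)
  }
})

test_that("annealing recovers exact optima on small graphs", {
  # two disjoint K4 cliques: optimal partition = the cliques, Q = 0.5
  g <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
  res <- modularity_annealing(g, seed = 1)
  expect_equal(res$q, 0.5, tolerance = 1e-12)
  expect_equal(res$n_modules, 2)
  expect_length(unique(res$membership[1:4]), 1)
  expect_length(unique(res$membership[5:8]), 1)

  # exhaustive oracle over all partitions of the 8 vertices
  qs <- vapply(all_partitions(8), function(mem) newman_modularity(g, mem), numeric(1))
  expect_equal(res$q, max(qs), tolerance = 1e-12)

  # complete graph: no modular structure
  kg <- igraph::make_full_graph(8)
  expect_lte(modularity_annealing(kg, seed = 2)$q, 0.05)

  # exhaustive oracle on a random small graph
  gr <- addnet:::.with_seed(9, igraph::sample_gnp(8, 0.35))
  if (igraph::ecount(gr) > 0) {
    qs2 <- vapply(all_partitions(8), function(mem) newman_modularity(gr, mem), numeric(1))
    expect_equal(modularity_annealing(gr, seed = 3)$q, max(qs2), tolerance = 1e-12)
  }
})

test_that("annealing recovers planted modules and beats greedy agglomeration", {
  pm <- matrix(0.05, 4, 4); diag(pm) <- 0.8
  for (s in 1:3) {
    g <- addnet:::.with_seed(40 + s,
      igraph::sample_sbm(80, pref.matrix = pm, block.sizes = rep(20, 4)))
    res <- modularity_annealing(g, seed = s)
    planted <- rep(1:4, each = 20)
    expect_gte(adjusted_rand(res$membership, planted), 0.9)
    greedy_q <- max(igraph::cluster_fast_greedy(g)$modularity)
    expect_gte(res$q, greedy_q - 1e-9)
  }
})
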