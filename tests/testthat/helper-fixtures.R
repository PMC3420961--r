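# Shared fixtures: small networks and fast parameter/config variants.

toy_network <- function(n = 5, p = 0.5, seed = 3, S = 1.5) {
  adj <- addnet:::.with_seed(seed, {
    a <- matrix(stats::rbinom(n * n, 1, p), n, n)
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    diag(a) <- 0
    a
  })
  structural_network(adj, coupling_strength = S)
}

# gain > 1 scales the single-neighbour input into the range where one
# coupled mass contributes a practically relevant share of a mass's drive
# (one edge supplies ~1% of the thalamic drive at gain 1, while a
# mid-degree region of the full network receives about tenfold that).
two_node_network <- function(S = 1.5, gain = 10) {
  structural_network(matrix(c(0, 1, 1, 0), 2), coupling_strength = S,
                     gain = gain)
}

line_plus_isolate <- function(S = 1.5) {
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
  structural_network(a, coupling_strength = S)
}

fast_config <- function(seed = 1, epoch_samples = 512, ...) {
  simulation_config(epoch_samples = epoch_samples, warmup_samples = 256,
                    seed = seed, ...)
}

cortical_degrees <- function() {
  tab <- cortical_degree_table()
  stats::setNames(tab$structural_degree, tab$region)
}

# Exhaustive set-partition enumeration (for exact modularity oracles on
# small graphs). Returns a list of integer membership vectors.
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (m in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, m)
  }
  out
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
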