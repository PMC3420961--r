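#' Threshold a weighted matrix to a target mean degree
#'
#' Keeps the `floor(target_mean_degree * N / 2)` strongest edges of a
#' symmetric weighted matrix, producing a binary, unweighted graph whose
#' mean degree equals the target up to rounding (the convention used to
#' compare functional networks of equal density with a structural network).
#' Ties at the cut are broken by lexicographic (row, column) pair order, so
#' the edge set is deterministic.
#'
#' @param w symmetric numeric matrix (weights; diagonal ignored).
#' @param target_mean_degree desired average degree (default 8).
#' @param on_short what to do when fewer nonzero weights exist than edges
#'   requested: `"error"` or `"warn"` (keep all nonzero edges).
#' @return An igraph undirected graph with `N` vertices.
#' @export
threshold_to_degree <- function(w, target_mean_degree = 8, on_short = c("error", "warn")) {
  on_short <- match.arg(on_short)
  w <- as.matrix(w)
  n <- nrow(w)
  if (target_mean_degree >= n - 1) stop("target mean degree too high for this graph")
  n_edges <- floor(target_mean_degree * n / 2)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  nz <- sum(wt > 0)
  if (nz < n_edges) {
    msg <- sprintf("only %d nonzero weights for %d requested edges", nz, n_edges)
    if (on_short == "error") stop(msg)
    warning(msg, "; keeping all nonzero edges")
    n_edges <- nz
  }
  # order: weight descending, then (row, col) ascending for determinism
  ord <- order(-wt, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_edges)]
  el <- ut[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (!is.null(rownames(w))) igraph::V(g)$name <- rownames(w)
  g
}

#' Clustering coefficient and characteristic path length
#'
#' Watts-Strogatz statistics of a simple undirected graph: the mean of the
#' per-node clustering coefficients (nodes with degree < 2 contribute 0) and
#' the mean shortest-path length over connected node pairs. Disconnected
#' pairs are excluded from the average and their fraction reported.
#'
#' @param graph an igraph graph.
#' @return List with `cp`, `lp`, `cp_local` (per node), and
#'   `disconnected_fraction`.
#' @export
clustering_and_path <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  cl <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  d <- igraph::distances(graph)
  ut <- d[upper.tri(d)]
  finite <- is.finite(ut)
  lp <- if (any(finite & ut > 0)) mean(ut[finite & ut > 0]) else NA_real_
  list(cp = mean(cl), lp = lp, cp_local = cl,
       disconnected_fraction = mean(!finite))
}

#' Small-world indices against degree-preserving surrogates
#'
#' gamma = Cp / <Cp of randomized surrogates>, lambda = Lp / <Lp of
#' surrogates>. Surrogates are degree-preserving double-edge-swap
#' randomizations (10 x edge count swaps each), generated reproducibly from
#' the seed.
#'
#' @param graph an igraph graph.
#' @param n_surrogates number of randomized surrogates (default 20).
#' @param seed RNG seed.
#' @return List with `gamma`, `lambda`, `cp`, `lp`, and the surrogate
#'   means/sds.
#' @export
normalized_small_world <- function(graph, n_surrogates = 20L, seed = 1L) {
  base <- clustering_and_path(graph)
  ne <- igraph::ecount(graph)
  if (ne < 2) stop("graph too small for surrogate randomization")
  stats <- .with_seed(.mix_seed(seed, 271L), {
    vapply(seq_len(n_surrogates), function(s) {
      gs <- igraph::rewire(graph, igraph::keeping_degseq(niter = 10 * ne))
      cs <- clustering_and_path(gs)
      c(cs$cp, cs$lp)
    }, numeric(2))
  })
  cp_r <- mean(stats[1, ]); lp_r <- mean(stats[2, ])
  list(gamma = base$cp / cp_r, lambda = base$lp / lp_r,
       cp = base$cp, lp = base$lp,
       cp_rand_mean = cp_r, cp_rand_sd = stats::sd(stats[1, ]),
       lp_rand_mean = lp_r, lp_rand_sd = stats::sd(stats[2, ]))
}

#' Newman modularity of a given partition
#'
#' Q = sum over modules of (within-module edge fraction) minus (expected
#' fraction from the degree sequence): `sum_m [e_m/E - (d_m/2E)^2]`.
#'
#' @param graph an igraph undirected graph with at least one edge.
#' @param membership integer module label per vertex.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
newman_modularity <- function(graph, membership) {
  E <- igraph::ecount(graph)
  if (E == 0) stop("graph has no edges")
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)
  .q_of(membership, adj, igraph::degree(graph), E)
}

#' Newman modularity maximized by simulated annealing
#'
#' Searches partitions of an undirected graph for maximal Newman modularity
#' Q using annealed single-node moves (to existing or new modules) with
#' occasional module merges and splits, geometric cooling, and repeated
#' restarts; the best partition over all restarts is returned. Deterministic
#' per seed.
#'
#' @param graph an igraph graph with at least one edge.
#' @param seed RNG seed.
#' @param n_restarts independent annealing restarts (default 5).
#' @param t0 initial temperature; `NULL` calibrates it to accept about half
#'   of uphill moves initially.
#' @param cooling geometric cooling factor per temperature step.
#' @param moves_per_t node moves attempted at each temperature.
#' @param patience stop a restart after this many temperature steps without
#'   improvement.
#' @return List with `q` (best modularity), `membership` (integer vector),
#'   and `n_modules`.
#' @export
modularity_annealing <- function(graph, seed = 1L, n_restarts = 5L,
                                 t0 = NULL, cooling = 0.95,
                                 moves_per_t = NULL, patience = 20L) {
  n <- igraph::vcount(graph)
  E <- igraph::ecount(graph)
  if (E < 1) stop("graph must have at least one edge")
  if (is.null(moves_per_t)) moves_per_t <- max(50L, 5L * n)
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)
  deg <- igraph::degree(graph)
  best_q <- -Inf; best_mem <- NULL
  for (rs in seq_len(n_restarts)) {
    res <- .with_seed(.mix_seed(seed, 7000L + rs), {
      .anneal_once(n, E, adj, deg, t0, cooling, moves_per_t, patience)
    })
    if (res$q > best_q) { best_q <- res$q; best_mem <- res$membership }
  }
  mem <- as.integer(factor(best_mem))
  list(q = best_q, membership = mem, n_modules = length(unique(mem)))
}

.anneal_once <- function(n, E, adj, deg, t0, cooling, moves_per_t, patience) {
  mem <- sample.int(max(2L, min(n, as.integer(ceiling(sqrt(n))))), n, replace = TRUE)
  # bookkeeping: per-module total degree, and Q decomposition
  dm <- tapply(deg, mem, sum)
  dm_vec <- numeric(n + 1L); dm_vec[as.integer(names(dm))] <- dm
  # within-module edge count per module is tracked implicitly via delta-Q
  q <- .q_of(mem, adj, deg, E)
  # calibrate t0 from the spread of random move deltas
  if (is.null(t0)) {
    deltas <- replicate(50, {
      v <- sample.int(n, 1); new <- sample.int(n, 1)
      abs(.delta_q_move(v, new, mem, adj, deg, E, dm_vec))
    })
    t0 <- max(stats::median(deltas), 1e-4) / log(2)
  }
  temp <- t0
  best_q <- q; best_mem <- mem
  stall <- 0L
  repeat {
    for (k in seq_len(moves_per_t)) {
      v <- sample.int(n, 1L)
      old <- mem[v]
      # propose: neighbour's module (biased, effective) or a fresh label
      nbrs <- adj[[v]]
      new <- if (length(nbrs) > 0 && stats::runif(1) < 0.85)
        mem[nbrs[sample.int(length(nbrs), 1L)]]
      else sample.int(n, 1L)
      if (new == old) next
      dq <- .delta_q_move(v, new, mem, adj, deg, E, dm_vec)
      if (dq >= 0 || stats::runif(1) < exp(dq / temp)) {
        dm_vec[old] <- dm_vec[old] - deg[v]
        dm_vec[new] <- dm_vec[new] + deg[v]
        mem[v] <- new
        q <- q + dq
      }
    }
    # occasional merge proposal
    mods <- unique(mem)
    if (length(mods) > 1) {
      ab <- sample(mods, 2L)
      mem2 <- mem; mem2[mem2 == ab[2]] <- ab[1]
      q2 <- .q_of(mem2, adj, deg, E)
      dq <- q2 - q
      if (dq >= 0 || stats::runif(1) < exp(dq / temp)) {
        mem <- mem2; q <- q2
        dm_vec[ab[1]] <- dm_vec[ab[1]] + dm_vec[ab[2]]; dm_vec[ab[2]] <- 0
      }
    }
    if (q > best_q + 1e-12) { best_q <- q; best_mem <- mem; stall <- 0L }
    else stall <- stall + 1L
    temp <- temp * cooling
    if (stall >= patience || temp < 1e-6) break
  }
  list(q = best_q, membership = best_mem)
}

.q_of <- function(mem, adj, deg, E) {
  within <- 0
  for (v in seq_along(adj)) within <- within + sum(mem[adj[[v]]] == mem[v])
  within <- within / 2
  dm <- tapply(deg, mem, sum)
  within / E - sum((dm / (2 * E))^2)
}

.delta_q_move <- function(v, new, mem, adj, deg, E, dm_vec) {
  old <- mem[v]
  nbrs <- adj[[v]]
  k_old <- sum(mem[nbrs] == old)
  k_new <- sum(mem[nbrs] == new)
  (k_new - k_old) / E -
    (deg[v] * (dm_vec[new] - dm_vec[old] + deg[v])) / (2 * E^2)
}
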