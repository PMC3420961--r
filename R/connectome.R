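#' Structural cortical network
#'
#' Builds the structural connectome object used by the simulator: region
#' labels, a symmetric binary adjacency matrix with zero diagonal, a per-edge
#' coupling matrix (initially `coupling_strength` times the adjacency), a
#' global integer conduction delay in samples, and a global gain.
#'
#' @param adjacency square 0/1 (or logical) matrix; symmetrized if needed.
#' @param labels region names; defaults to `R1..RN` or the matrix dimnames.
#' @param coupling_strength global initial inter-mass coupling S (>= 0).
#' @param delay_samples global conduction delay, in samples (positive integer).
#' @param gain global dimensionless gain on the coupling pathway.
#' @return An object of class `structural_network`.
#' @export
structural_network <- function(adjacency, labels = NULL,
                               coupling_strength = 1.5,
                               delay_samples = 1L, gain = 1) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (any(adjacency < 0)) {
    bad <- which(adjacency < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative adjacency entry at (%d, %d)", bad[1], bad[2]))
  }
  adjacency <- (adjacency != 0) * 1
  if (any(diag(adjacency) != 0)) {
    warning("self-loops on the diagonal were removed")
    diag(adjacency) <- 0
  }
  n_asym <- sum(adjacency != t(adjacency)) / 2
  if (n_asym > 0) {
    warning(sprintf("adjacency symmetrized (logical OR); %d cell pair(s) repaired", n_asym))
    adjacency <- ((adjacency + t(adjacency)) > 0) * 1
  }
  if (is.null(labels)) labels <- rownames(adjacency)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  if (length(labels) != n) stop("labels length must match matrix dimension")
  if (coupling_strength < 0) stop("coupling_strength must be >= 0")
  delay_samples <- as.integer(delay_samples)
  if (delay_samples < 1L) stop("delay_samples must be a positive integer")
  dimnames(adjacency) <- list(labels, labels)
  structure(list(
    labels = labels,
    adjacency = adjacency,
    coupling = coupling_strength * adjacency,
    coupling_strength = coupling_strength,
    delay_samples = delay_samples,
    gain = gain
  ), class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  k <- structural_degree(x)
  cat(sprintf("Structural network: %d regions, %d edges, mean degree %.2f\n",
              length(x$labels), sum(x$adjacency) / 2, mean(k)))
  cat(sprintf("  coupling S = %g, delay = %d sample(s), gain = %g\n",
              x$coupling_strength, x$delay_samples, x$gain))
  invisible(x)
}

#' Structural degree of each region
#'
#' @param network a `structural_network`.
#' @return Named integer vector of per-region degrees.
#' @export
structural_degree <- function(network) {
  k <- as.integer(rowSums(network$adjacency))
  names(k) <- network$labels
  k
}

#' Per-region node strength of the (possibly degraded) coupling matrix
#'
#' @param network a `structural_network`.
#' @return Named numeric vector: row sums of the coupling matrix.
#' @export
node_strength <- function(network) {
  s <- rowSums(network$coupling)
  names(s) <- network$labels
  s
}

#' Load a structural network from a delimited text file
#'
#' Accepts either a whitespace- or comma-delimited square numeric matrix
#' (optional header row and optional leading label column), or a two-column
#' edge list of region labels. Asymmetric matrix input is symmetrized by
#' logical OR with a warning; diagonal entries are zeroed with a warning.
#' A two-column file is read as an edge list when its entries are
#' non-numeric or when it cannot be a square matrix.
#'
#' @param path file path.
#' @param ... further arguments to [structural_network()] (coupling strength,
#'   delay, gain).
#' @return A `structural_network`.
#' @export
load_adjacency <- function(path, ...) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  two_col <- ncol(df) == 2
  nonnum <- !all(vapply(df, is.numeric, logical(1)))
  if (two_col && (nonnum || nrow(df) != 2)) {
    df <- utils::read.table(path, sep = sep, header = FALSE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    el <- cbind(as.character(df[[1]]), as.character(df[[2]]))
    labels <- sort(unique(c(el)))
    m <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    m[el] <- 1
    m[el[, c(2, 1), drop = FALSE]] <- 1
    return(structural_network(m, labels = labels, ...))
  }
  labels <- NULL
  if (ncol(df) >= 1 && !is.numeric(df[[1]])) {
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else if (has_header) {
    labels <- colnames(df)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("adjacency file does not parse to a numeric matrix")
  if (nrow(m) != ncol(m))
    stop(sprintf("adjacency must be square (got %d x %d)", nrow(m), ncol(m)))
  rownames(m) <- colnames(m) <- NULL
  structural_network(m, labels = labels, ...)
}

#' Region labels and structural degrees of the packaged 78-region fixture
#'
#' Returns the packaged table of 78 human cortical region labels with their
#' structural degrees (sum 658, mean about 8.44), ranked in descending
#' degree. This degree sequence is the input for the degree-matched synthetic
#' connectome generator.
#'
#' @return A data.frame with columns `region` and `structural_degree`.
#' @export
#' @examples
#' head(cortical_degree_table(), 3)
cortical_degree_table <- function() {
  path <- system.file("extdata", "cortical_regions_78.tsv", package = "addnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate a synthetic connectome matching a degree sequence
#'
#' Samples a simple undirected graph whose degree sequence equals the input
#' exactly (configuration-model pairing with edge-swap repair, via igraph's
#' Viger-Latapy sampler), then randomizes it further with degree-preserving
#' double-edge swaps. Reproducible per seed.
#'
#' @param degree_sequence integer vector; must be graphical (Erdos-Gallai).
#' @param seed integer RNG seed.
#' @param labels optional region labels (defaults to the packaged cortical
#'   labels when the sequence has length 78 and matches the fixture).
#' @param ... further arguments to [structural_network()].
#' @return A `structural_network` whose degrees equal `degree_sequence`.
#' @export
generate_degree_matched <- function(degree_sequence, seed = 1L, labels = NULL, ...) {
  degree_sequence <- as.integer(degree_sequence)
  if (sum(degree_sequence) %% 2L != 0L)
    stop("degree sequence has odd sum; not graphical")
  if (!igraph::is_graphical(degree_sequence))
    stop("degree sequence is not graphical (fails the Erdos-Gallai condition)")
  if (is.null(labels)) {
    tab <- tryCatch(cortical_degree_table(), error = function(e) NULL)
    if (!is.null(tab) && length(degree_sequence) == nrow(tab) &&
        identical(as.integer(tab$structural_degree), degree_sequence))
      labels <- tab$region
  }
  g <- .with_seed(.mix_seed(seed, 815L), {
    g0 <- igraph::sample_degseq(degree_sequence, method = "vl")
    if (igraph::ecount(g0) > 1)
      g0 <- igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * igraph::ecount(g0)))
    g0
  })
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  net <- structural_network(adj, labels = labels, ...)
  stopifnot(identical(as.integer(unname(structural_degree(net))), degree_sequence))
  net
}

#' Degree-based hub classification
#'
#' Sorts regions by structural degree ascending and cuts them into
#' equal-sized bins (six by default); the top bin is the hub set. When the
#' region count is not divisible by the bin count, the remainder is spread
#' over the lowest bins (largest-remainder rule), keeping the hub bin at
#' exactly `floor(n / n_bins)` regions. Ties at bin boundaries are broken by
#' a stable sort on (degree, label), so the partition is deterministic and
#' invariant to input row order.
#'
#' @param network a `structural_network`, or a named integer degree vector.
#' @param n_bins number of bins (default 6).
#' @return An object of class `hub_partition`: list with `bins` (list of
#'   label vectors, ascending mean degree), `hubs`, `non_hubs`, and the
#'   per-region `bin` index in input order.
#' @export
#' @examples
#' tab <- cortical_degree_table()
#' hp <- classify_hubs(stats::setNames(tab$structural_degree, tab$region))
#' length(hp$hubs)  # 13
classify_hubs <- function(network, n_bins = 6L) {
  k <- if (inherits(network, "structural_network")) structural_degree(network)
       else network
  if (is.null(names(k))) names(k) <- paste0("R", seq_along(k))
  n <- length(k)
  if (n < n_bins) stop("fewer regions than bins")
  ord <- order(k, names(k))   # stable: degree, then label
  base <- n %/% n_bins; rem <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n); bin[ord] <- bin_sorted
  bins <- split(names(k)[ord], bin_sorted)
  names(bins) <- paste0("bin", seq_len(n_bins))
  hubs <- bins[[n_bins]]
  structure(list(
    bins = bins,
    hubs = hubs,
    non_hubs = setdiff(names(k), hubs),
    bin = stats::setNames(bin, names(k)),
    degree = k
  ), class = "hub_partition")
}

#' @export
print.hub_partition <- function(x, ...) {
  cat(sprintf("Hub partition: %d bins, %d hubs / %d non-hubs\n",
              length(x$bins), length(x$hubs), length(x$non_hubs)))
  cat("  hubs:", paste(utils::head(x$hubs, 6), collapse = ", "),
      if (length(x$hubs) > 6) "..." else "", "\n")
  invisible(x)
}
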