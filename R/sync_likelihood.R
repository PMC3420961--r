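#' Synchronization likelihood parameters
#'
#' Tuning constants for the recurrence-based synchronization likelihood
#' (SL). When a frequency band is given, the constants are derived from its
#' content following the standard auto-tuning recipe: `lag =
#' sample_rate/(3*high)`, `m = 3*(high/low) + 1` (capped), `w1 =
#' 2*lag*(m-1)`, `w2 = w1 + 10/p_ref`. All derived values can be overridden.
#'
#' @param sample_rate Hz.
#' @param band `c(low, high)` Hz used for auto-tuning; `NULL` to pass every
#'   constant explicitly.
#' @param p_ref reference recurrence probability (default 0.01).
#' @param embed_dim embedding dimension m (>= 2).
#' @param lag embedding lag in samples.
#' @param w1 Theiler exclusion window (samples); must be >= lag*(m-1).
#' @param w2 outer window (samples); must exceed `w1`.
#' @param ref_step stride between reference time points (speed/precision
#'   trade-off; 1 = every embedded point).
#' @param max_embed_dim cap on the auto-tuned m (broadband ratios would
#'   otherwise demand impractically high dimensions).
#' @return An object of class `sl_params`.
#' @export
sl_params <- function(sample_rate, band = NULL, p_ref = 0.01,
                      embed_dim = NULL, lag = NULL, w1 = NULL, w2 = NULL,
                      ref_step = 4L, max_embed_dim = 10L) {
  if (p_ref <= 0 || p_ref >= 0.5) stop("p_ref must be in (0, 0.5)")
  if (!is.null(band)) {
    if (band[2] <= band[1]) stop("band edges inverted")
    if (is.null(lag)) lag <- max(1L, as.integer(round(sample_rate / (3 * band[2]))))
    if (is.null(embed_dim))
      embed_dim <- min(max_embed_dim, max(2L, as.integer(round(3 * band[2] / band[1]) + 1L)))
  }
  if (is.null(lag) || is.null(embed_dim))
    stop("either supply a band or both embed_dim and lag")
  if (embed_dim < 2) stop("embed_dim must be >= 2")
  if (is.null(w1)) w1 <- 2L * lag * (embed_dim - 1L)
  if (is.null(w2)) w2 <- w1 + as.integer(round(10 / p_ref))
  if (w1 < lag * (embed_dim - 1L)) stop("w1 must be >= lag*(m-1)")
  if (w2 <= w1) stop("w2 must exceed w1")
  structure(list(embed_dim = as.integer(embed_dim), lag = as.integer(lag),
                 w1 = as.integer(w1), w2 = as.integer(w2), p_ref = p_ref,
                 ref_step = as.integer(ref_step),
                 sample_rate = sample_rate, band = band),
            class = "sl_params")
}

#' @export
print.sl_params <- function(x, ...) {
  cat(sprintf("SL parameters: m = %d, lag = %d, w1 = %d, w2 = %d, p_ref = %g, ref step %d\n",
              x$embed_dim, x$lag, x$w1, x$w2, x$p_ref, x$ref_step))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass. The design edges are
#' padded outward by 35% of the bandwidth so that signal content exactly at
#' a band edge is passed essentially unattenuated; the effective order is
#' doubled by the two passes.
#'
#' @param trace numeric vector.
#' @param band `c(low, high)` Hz.
#' @param sample_rate Hz.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered trace, same length.
#' @export
band_filter <- function(trace, band, sample_rate, order = 4L) {
  if (band[2] <= band[1]) stop("band edges inverted")
  nyq <- sample_rate / 2
  if (band[2] >= nyq) stop("band exceeds Nyquist")
  pad <- 0.35 * (band[2] - band[1])
  lo <- max(band[1] - pad, 0.1)
  hi <- min(band[2] + pad, nyq * 0.98)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, trace - mean(trace)))
}

# Time-delay embedding: rows are embedded vectors.
.embed_delay <- function(x, m, lag) {
  n_emb <- length(x) - (m - 1L) * lag
  if (n_emb < 2) stop("trace too short for this embedding")
  idx <- seq_len(n_emb)
  out <- matrix(0, n_emb, m)
  for (d in seq_len(m)) out[, d] <- x[idx + (d - 1L) * lag]
  out
}

# For one channel: per reference time, the set of recurrent neighbours
# (indices into the embedding) chosen by exact rank selection so that the
# recurrence fraction within the (w1, w2) window equals p_ref. Chebyshev
# metric. Returns a list with refs, neighbour index list, and per-ref counts.
.sl_recurrences <- function(x, params) {
  m <- params$embed_dim; lag <- params$lag
  emb <- .embed_delay(x, m, lag)
  n_emb <- nrow(emb)
  if (stats::sd(x) == 0) stop("constant trace: synchronization likelihood undefined")
  refs <- seq(1L, n_emb, by = params$ref_step)
  nb <- vector("list", length(refs))
  n_hit <- integer(length(refs))
  for (q in seq_along(refs)) {
    i <- refs[q]
    lo1 <- max(1L, i - params$w2); hi1 <- i - params$w1 - 1L
    lo2 <- i + params$w1 + 1L; hi2 <- min(n_emb, i + params$w2)
    cand <- c(if (hi1 >= lo1) lo1:hi1, if (hi2 >= lo2) lo2:hi2)
    if (length(cand) < 2) { nb[[q]] <- integer(0); next }
    d <- abs(emb[cand, 1L] - emb[i, 1L])
    for (dd in 2:m) d <- pmax(d, abs(emb[cand, dd] - emb[i, dd]))
    k <- max(1L, as.integer(round(params$p_ref * length(cand))))
    nb[[q]] <- cand[order(d)[seq_len(k)]]
    n_hit[q] <- k
  }
  list(refs = refs, neighbours = nb, n_hit = n_hit, n_emb = n_emb)
}

#' Pairwise synchronization likelihood
#'
#' Recurrence-based measure of generalized synchronization between two
#' signals, sensitive to linear and nonlinear coupling. Both signals are
#' time-delay embedded; for each reference time, each channel's critical
#' distance is chosen by exact rank selection so that its recurrence
#' fraction within the Theiler-excluded window equals `p_ref`
#' (Chebyshev metric). The SL is the probability that the two channels are
#' simultaneously recurrent, given that one is — estimated as the ratio of
#' summed joint recurrences to summed per-channel recurrences, which is
#' symmetric in the two signals. Values range from about `p_ref`
#' (independent signals) to 1 (identical signals).
#'
#' @param x,y equal-length numeric traces (already band-filtered if a
#'   band-limited SL is wanted).
#' @param params an `sl_params`.
#' @return SL value in \[0, 1\].
#' @export
sl_pairwise <- function(x, y, params) {
  if (length(x) != length(y)) stop("traces differ in length")
  min_len <- params$w2 + (params$embed_dim - 1L) * params$lag + 1L
  if (length(x) < min_len)
    stop("traces too short for these SL parameters (need >= ", min_len, " samples)")
  rx <- .sl_recurrences(x, params)
  ry <- .sl_recurrences(y, params)
  joint <- sum(vapply(seq_along(rx$refs), function(q)
    length(intersect(rx$neighbours[[q]], ry$neighbours[[q]])), integer(1)))
  denom <- sum(rx$n_hit)
  if (denom == 0) return(NA_real_)
  joint / denom
}

#' Band-limited functional connectivity matrix
#'
#' Filters every region's trace to the requested band, computes the
#' synchronization likelihood for all unordered region pairs (sharing the
#' per-channel recurrence structure across pairs, so the cost is linear in
#' regions for the embedding work), and returns the symmetric SL matrix with
#' zero diagonal plus per-region functional degrees (row sums of weights).
#'
#' @param traces samples x regions matrix.
#' @param band `c(low, high)` Hz, or `NULL` to skip filtering.
#' @param params an `sl_params`; when `NULL`, auto-tuned from `band` and
#'   `sample_rate`.
#' @param sample_rate Hz (required when `params` is `NULL`).
#' @param labels region names.
#' @return An object of class `functional_network`: list with `sl_matrix`,
#'   `functional_degree`, `band`, `params`.
#' @export
functional_network <- function(traces, band = NULL, params = NULL,
                               sample_rate = NULL, labels = colnames(traces)) {
  traces <- as.matrix(traces)
  n <- ncol(traces)
  if (n < 2) stop("need at least 2 regions")
  if (is.null(params)) {
    if (is.null(sample_rate)) stop("supply sample_rate when params is NULL")
    if (is.null(band)) stop("supply band or params")
    params <- sl_params(sample_rate, band = band)
  }
  if (!is.null(band))
    traces <- apply(traces, 2, band_filter, band = band,
                    sample_rate = params$sample_rate)
  recs <- lapply(seq_len(n), function(i) {
    tryCatch(.sl_recurrences(traces[, i], params),
             error = function(e) stop("region ", i, ": ", conditionMessage(e)))
  })
  n_emb <- recs[[1]]$n_emb
  n_refs <- length(recs[[1]]$refs)
  denom <- sum(recs[[1]]$n_hit)
  # sparse joint counting: one column per region, rows index (ref, neighbour)
  ii <- integer(0); jj <- integer(0)
  for (ch in seq_len(n)) {
    r <- recs[[ch]]
    lens <- lengths(r$neighbours)
    lin <- unlist(r$neighbours, use.names = FALSE) +
      rep((seq_len(n_refs) - 1) * n_emb, lens)
    ii <- c(ii, lin); jj <- c(jj, rep(ch, length(lin)))
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(as.double(n_refs) * n_emb, n))
  counts <- as.matrix(Matrix::crossprod(M))
  sl <- counts / denom
  diag(sl) <- 0
  dimnames(sl) <- list(labels, labels)
  structure(list(sl_matrix = sl,
                 functional_degree = rowSums(sl),
                 band = band, params = params),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("Functional network: %d regions, band %s, mean SL %.4f\n",
              nrow(x$sl_matrix),
              if (is.null(x$band)) "broadband" else paste(x$band, collapse = "-"),
              mean(x$sl_matrix[upper.tri(x$sl_matrix)])))
  invisible(x)
}
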