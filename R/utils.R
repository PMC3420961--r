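# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Pearson product-moment correlation with contract checks; thin wrapper kept
# as the single place correlations are computed for reports.
#' Pearson correlation
#'
#' Product-moment correlation between two equal-length numeric vectors, with
#' explicit contract checks (length >= 3, finite, non-constant input).
#'
#' @param x,y numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: inputs differ in length")
  if (length(x) < 3) stop("pearson: need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("pearson: non-finite input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson: constant input, correlation undefined")
  stats::cor(x, y)
}
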