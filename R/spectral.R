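#' Canonical EEG frequency bands
#'
#' The six analysis bands, in Hz, as half-open intervals \[low, high):
#' delta 0.5-4, theta 4-8, lower alpha 8-10, higher alpha 10-13, beta 13-30,
#' gamma 30-45. Total (broadband) power is integrated over \[0, 70) Hz.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
canonical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8),
       lower_alpha = c(8, 10), higher_alpha = c(10, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

#' One-sided power spectral density
#'
#' Mean-removed periodogram (optionally Hann-windowed). The raw periodogram
#' is Parseval-consistent: the PSD integrated over frequency equals the
#' signal variance. The Hann window trades that exactness for reduced
#' leakage and is the default for band summaries averaged over epochs.
#'
#' @param trace numeric vector, length >= 256.
#' @param sample_rate Hz.
#' @param window `"none"` (raw periodogram) or `"hann"`.
#' @return An object of class `psd`: list with `freq` (Hz, excluding DC),
#'   `power` (density, unit^2/Hz), `df` (bin width), `sample_rate`.
#' @export
power_spectrum <- function(trace, sample_rate, window = c("hann", "none")) {
  window <- match.arg(window)
  n <- length(trace)
  if (n < 256) stop("trace too short for spectral analysis (need >= 256 samples)")
  if (any(!is.finite(trace))) stop("non-finite values in trace")
  x <- trace - mean(trace)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
    x <- x * w / sqrt(mean(w^2))   # preserve average power
  }
  X <- stats::fft(x)
  half <- n %/% 2
  # one-sided density: non-DC, non-Nyquist bins doubled
  p <- (Mod(X[2:(half + 1)])^2) / (sample_rate * n)
  p <- 2 * p
  if (n %% 2 == 0) p[half] <- p[half] / 2
  structure(list(freq = (1:half) * sample_rate / n, power = p,
                 df = sample_rate / n, sample_rate = sample_rate),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("PSD: %d bins, df = %.3f Hz, peak at %.2f Hz\n",
              length(x$freq), x$df, x$freq[which.max(x$power)]))
  invisible(x)
}

#' Band power from a PSD
#'
#' Integrates the PSD over a half-open band \[low, high) Hz.
#'
#' @param psd a `psd` object.
#' @param band `c(low, high)` in Hz.
#' @return Absolute power (signal units squared).
#' @export
band_power <- function(psd, band) {
  if (band[2] <= band[1]) stop("band edges inverted")
  if (band[2] > psd$sample_rate / 2 + 1e-9) stop("band exceeds Nyquist")
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  sum(psd$power[sel]) * psd$df
}

#' Total broadband power
#'
#' Absolute power integrated over \[0, `upper`) Hz (default 70).
#'
#' @param psd a `psd` object.
#' @param upper upper integration edge in Hz.
#' @return Absolute power.
#' @export
total_power <- function(psd, upper = 70) {
  sum(psd$power[psd$freq < upper]) * psd$df
}

#' Alpha peak frequency
#'
#' Frequency of the PSD maximum within a window around the alpha band
#' (default 4-13 Hz, wide enough to register slowing below 8 Hz).
#'
#' @param psd a `psd` object.
#' @param range `c(low, high)` search window in Hz.
#' @return Frequency in Hz.
#' @export
alpha_peak <- function(psd, range = c(4, 13)) {
  sel <- psd$freq >= range[1] & psd$freq <= range[2]
  psd$freq[sel][which.max(psd$power[sel])]
}

#' Spectral summary of a trace
#'
#' Total power (0-70 Hz), the six canonical band powers, and the alpha peak
#' frequency, from a single PSD.
#'
#' @param trace numeric vector.
#' @param sample_rate Hz.
#' @param bands named list of band edges; defaults to [canonical_bands()].
#' @param window passed to [power_spectrum()].
#' @return An object of class `spectral_summary`: list with `total_power`,
#'   `band_powers` (named numeric), `alpha_peak_hz`.
#' @export
summarize_bands <- function(trace, sample_rate, bands = canonical_bands(),
                            window = "hann") {
  psd <- power_spectrum(trace, sample_rate, window = window)
  bp <- vapply(bands, function(b) band_power(psd, b), numeric(1))
  structure(list(total_power = total_power(psd),
                 band_powers = bp,
                 alpha_peak_hz = alpha_peak(psd)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("Spectral summary: total power %.4g, alpha peak %.2f Hz\n",
              x$total_power, x$alpha_peak_hz))
  print(round(x$band_powers, 4))
  invisible(x)
}
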