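#' Neural mass model parameters
#'
#' Constructs the parameter set of a single lumped-population neural mass of
#' the alpha rhythm: an excitatory and an inhibitory population, each
#' characterized by an average membrane potential and a pulse density.
#' Membrane potentials are converted to pulse densities by sigmoid functions;
#' pulse densities are converted to membrane potentials by
#' difference-of-exponentials impulse responses.
#'
#' The defaults place an uncoupled, noise-driven mass in the alpha regime:
#' its simulated potential has a spectral peak near 10 Hz and the excitatory
#' pulse density fluctuates around roughly 400 spikes/s. All constants are
#' plain numbers in the units given below and may be overridden one by one.
#'
#' @param c1 dimensionless coupling, excitatory -> inhibitory population.
#' @param c2 dimensionless coupling, inhibitory -> excitatory population.
#' @param he_gain,he_decay,he_rise excitatory impulse-response amplitude (mV
#'   per unit pulse density) and its slow/fast rate constants (1/s). The
#'   kernel is `he_gain * (exp(-he_decay*t) - exp(-he_rise*t))`, so
#'   `he_rise > he_decay` is required for a positive response.
#' @param hi_gain,hi_decay,hi_rise inhibitory counterparts.
#' @param sigmoid_e,sigmoid_i named numeric triples
#'   `c(max_rate=, threshold=, steepness=)` (spikes/s, mV, 1/mV) for the
#'   excitatory and inhibitory potential-to-rate sigmoids.
#' @param pt gain on the thalamic input pathway (degraded by the
#'   activity-dependent rule alongside `c1` and `c2`).
#' @param thalamic_mean,thalamic_sd mean and standard deviation of the
#'   Gaussian thalamic pulse density P(t) (spikes/s), truncated at zero.
#' @param sample_rate sampling rate of the simulation (Hz).
#'
#' @return An object of class `nmm_params` (a validated list).
#' @export
#' @examples
#' p <- nmm_params()
#' p$sample_rate
nmm_params <- function(c1 = NULL, c2 = NULL,
                       he_gain = NULL, he_decay = 55, he_rise = 605,
                       hi_gain = 22, hi_decay = 20, hi_rise = 45,
                       sigmoid_e = NULL,
                       sigmoid_i = NULL,
                       pt = 1,
                       thalamic_mean = NULL, thalamic_sd = NULL,
                       sample_rate = 500) {
  d <- .nmm_defaults()
  if (is.null(c1)) c1 <- d$c1
  if (is.null(c2)) c2 <- d$c2
  if (is.null(he_gain)) he_gain <- d$he_gain
  if (is.null(thalamic_mean)) thalamic_mean <- d$thalamic_mean
  if (is.null(thalamic_sd)) thalamic_sd <- d$thalamic_sd
  if (is.null(sigmoid_e)) sigmoid_e <- d$sigmoid_e
  if (is.null(sigmoid_i)) sigmoid_i <- d$sigmoid_i
  sigmoid_e <- .check_sigmoid(sigmoid_e, "sigmoid_e")
  sigmoid_i <- .check_sigmoid(sigmoid_i, "sigmoid_i")
  p <- list(c1 = c1, c2 = c2,
            he_gain = he_gain, he_decay = he_decay, he_rise = he_rise,
            hi_gain = hi_gain, hi_decay = hi_decay, hi_rise = hi_rise,
            sigmoid_e = sigmoid_e, sigmoid_i = sigmoid_i,
            pt = pt,
            thalamic_mean = thalamic_mean, thalamic_sd = thalamic_sd,
            sample_rate = sample_rate)
  validate_nmm_params(p)
  structure(p, class = "nmm_params")
}

# Calibrated defaults; filled in after numeric calibration of the coupled
# regime (see the methods vignette for the rationale of each value).
.nmm_defaults <- function() {
  list(
    c1 = 84.15,
    c2 = 0.06,
    he_gain = 0.042 / 4.5,
    thalamic_mean = 64800,
    thalamic_sd = 9000,
    sigmoid_e = c(max_rate = 922, threshold = 5.25, steepness = 0.93),
    sigmoid_i = c(max_rate = 450, threshold = 6.90, steepness = 1.4)
  )
}

.check_sigmoid <- function(s, what) {
  if (length(s) != 3 || !is.numeric(s))
    stop(what, " must be a numeric triple (max_rate, threshold, steepness)")
  if (is.null(names(s)) || !all(c("max_rate", "threshold", "steepness") %in% names(s)))
    names(s) <- c("max_rate", "threshold", "steepness")
  if (s[["max_rate"]] <= 0 || s[["steepness"]] <= 0)
    stop(what, ": max_rate and steepness must be strictly positive")
  s[c("max_rate", "threshold", "steepness")]
}

#' @export
print.nmm_params <- function(x, ...) {
  cat("Neural mass parameters (alpha-rhythm lumped model)\n")
  cat(sprintf("  c1 = %.4g  c2 = %.4g  pt = %.4g\n", x$c1, x$c2, x$pt))
  cat(sprintf("  he: gain %.4g mV, decay %.4g /s, rise %.4g /s\n",
              x$he_gain, x$he_decay, x$he_rise))
  cat(sprintf("  hi: gain %.4g mV, decay %.4g /s, rise %.4g /s\n",
              x$hi_gain, x$hi_decay, x$hi_rise))
  cat(sprintf("  sigmoid_e: max %.4g /s, threshold %.4g mV, steepness %.4g /mV\n",
              x$sigmoid_e[["max_rate"]], x$sigmoid_e[["threshold"]],
              x$sigmoid_e[["steepness"]]))
  cat(sprintf("  sigmoid_i: max %.4g /s, threshold %.4g mV, steepness %.4g /mV\n",
              x$sigmoid_i[["max_rate"]], x$sigmoid_i[["threshold"]],
              x$sigmoid_i[["steepness"]]))
  cat(sprintf("  thalamic P(t): mean %.4g, sd %.4g spikes/s; sample rate %g Hz\n",
              x$thalamic_mean, x$thalamic_sd, x$sample_rate))
  invisible(x)
}

#' Validate a neural mass parameter set
#'
#' Checks positivity of gains and rate constants, distinctness of the
#' rise/decay constants (the difference-of-exponentials kernel degenerates
#' when they coincide), and that the sample rate resolves the 0-70 Hz
#' analysis window.
#'
#' @param p an `nmm_params` object or plain list with the same fields.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_nmm_params <- function(p) {
  pos <- c("he_gain", "he_decay", "he_rise", "hi_gain", "hi_decay", "hi_rise",
           "sample_rate")
  for (f in pos)
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop("nmm_params: ", f, " must be strictly positive")
  if (p$he_decay == p$he_rise || p$hi_decay == p$hi_rise)
    stop("nmm_params: rise and decay rates must differ (degenerate kernel)")
  if (p$thalamic_sd < 0) stop("nmm_params: thalamic_sd must be >= 0")
  if (p$sample_rate <= 140)
    stop("nmm_params: sample_rate must exceed 140 Hz (2 x the 70 Hz analysis edge)")
  invisible(TRUE)
}

#' Sigmoid potential-to-rate conversion
#'
#' Converts an average membrane potential to a pulse density through a
#' logistic sigmoid: `max_rate / (1 + exp(-steepness * (v - threshold)))`.
#'
#' @param v membrane potential (mV); may be a vector.
#' @param params sigmoid triple `c(max_rate, threshold, steepness)`.
#' @return Pulse density in \[0, max_rate\] (spikes/s).
#' @export
#' @examples
#' nmm_sigmoid(6, c(max_rate = 1000, threshold = 6, steepness = 0.9)) # 500
nmm_sigmoid <- function(v, params) {
  params <- .check_sigmoid(params, "params")
  if (any(!is.finite(v)))
    stop("nmm_sigmoid: non-finite membrane potential (numerical blow-up upstream?)")
  params[["max_rate"]] /
    (1 + exp(-params[["steepness"]] * (v - params[["threshold"]])))
}

#' Difference-of-exponentials impulse response
#'
#' Evaluates `h(t) = gain * (exp(-decay t) - exp(-rise t))` for `t >= 0`,
#' the synaptic impulse response used for both populations. Requires
#' `rise > decay` so the kernel is positive, causal (h(0) = 0), and has a
#' single interior maximum at `log(rise/decay) / (rise - decay)`.
#'
#' @param t time (s), vectorized, non-negative.
#' @param gain amplitude scale (mV).
#' @param rise,decay rate constants (1/s), `rise != decay`.
#' @return Kernel values (mV).
#' @export
impulse_response <- function(t, gain, rise, decay) {
  if (rise == decay) stop("impulse_response: rise must differ from decay")
  if (any(t < 0)) stop("impulse_response: t must be non-negative")
  gain * (exp(-decay * t) - exp(-rise * t))
}

# ZOH-exact discretization coefficients for y' = -a*y + u at step dt:
# y[n+1] = d*y[n] + k*u[n],  d = exp(-a dt), k = (1 - d)/a.
.filter_coef <- function(a, dt) list(d = exp(-a * dt), k = (1 - exp(-a * dt)) / a)

#' Initial state of one or more neural masses
#'
#' Allocates the internal state: for each mass, the two first-order stages of
#' each of the three synaptic filters (thalamic+cortical input onto the
#' excitatory population, inhibitory feedback onto the excitatory population,
#' excitatory drive onto the inhibitory population), plus the current
#' membrane potentials and pulse densities.
#'
#' @param n_regions number of masses.
#' @param params an `nmm_params` object (used for the resting rates).
#' @return An object of class `nmm_state`: a list of numeric vectors of
#'   length `n_regions`.
#' @export
nmm_state <- function(n_regions, params) {
  z <- numeric(n_regions)
  structure(list(
    ye1 = z, ye2 = z,   # he filter, input pathway (thalamic + cortical)
    yi1 = z, yi2 = z,   # hi filter, inhibitory feedback
    yc1 = z, yc2 = z,   # he filter, excitatory -> inhibitory pathway
    ve = z, vi = z,
    e_rate = rep(nmm_sigmoid(0, params$sigmoid_e), n_regions),
    i_rate = rep(nmm_sigmoid(0, params$sigmoid_i), n_regions)
  ), class = "nmm_state")
}

#' Resting fixed point of a neural mass
#'
#' Solves the deterministic self-consistent resting state of a single mass
#' given a constant external drive (thalamic mean plus any cortical input),
#' by damped fixed-point iteration on the pulse densities.
#'
#' @param params an `nmm_params` object.
#' @param external_input constant additional pulse density (spikes/s).
#' @param thalamic constant thalamic drive; defaults to 0 (quiescent input).
#' @return A list with elements `ve`, `vi`, `e_rate`, `i_rate` and an
#'   `nmm_state` positioned at the fixed point (`state`).
#' @export
nmm_rest_state <- function(params, external_input = 0, thalamic = 0) {
  ge <- params$he_gain * (1 / params$he_decay - 1 / params$he_rise)
  gi <- params$hi_gain * (1 / params$hi_decay - 1 / params$hi_rise)
  e <- nmm_sigmoid(0, params$sigmoid_e)
  i <- nmm_sigmoid(0, params$sigmoid_i)
  for (k in 1:2000) {
    vi <- ge * params$c1 * e
    i <- 0.5 * i + 0.5 * nmm_sigmoid(vi, params$sigmoid_i)
    ve <- ge * (params$pt * thalamic + external_input) - gi * params$c2 * i
    e <- 0.5 * e + 0.5 * nmm_sigmoid(ve, params$sigmoid_e)
  }
  st <- nmm_state(1L, params)
  u_e <- params$pt * thalamic + external_input
  st$ye1 <- u_e / params$he_decay; st$ye2 <- u_e / params$he_rise
  st$yi1 <- params$c2 * i / params$hi_decay; st$yi2 <- params$c2 * i / params$hi_rise
  st$yc1 <- params$c1 * e / params$he_decay; st$yc2 <- params$c1 * e / params$he_rise
  st$ve <- ve; st$vi <- vi; st$e_rate <- e; st$i_rate <- i
  list(ve = ve, vi = vi, e_rate = e, i_rate = i, state = st)
}

#' Advance neural masses by one sample
#'
#' One fixed-step update of the two-population loop for `n` masses in
#' lockstep. Each excitatory population receives its (gain-scaled) external
#' input plus thalamic drive through the excitatory kernel and the `c2`-scaled
#' inhibitory pulse density through the inhibitory kernel; each inhibitory
#' population receives the `c1`-scaled excitatory pulse density through the
#' excitatory kernel. The linear filters are advanced by their exact
#' zero-order-hold discretization; the sigmoids are instantaneous. The update
#' is fully deterministic given the state, the inputs, and the supplied
#' thalamic noise draw.
#'
#' @param state an `nmm_state` (vectors of length n).
#' @param params an `nmm_params` object (global constants).
#' @param external_input per-region summed cortical pulse density (spikes/s),
#'   already delayed and coupling-scaled.
#' @param noise_draw per-region standard-normal draw for the thalamic input;
#'   `P(t) = max(0, thalamic_mean + thalamic_sd * noise_draw)`.
#' @param c1,c2,pt optional per-region coupling vectors overriding the global
#'   constants (used by the degeneration rule); recycled to length n.
#' @return The advanced `nmm_state`.
#' @export
step_mass <- function(state, params, external_input = 0, noise_draw = 0,
                      c1 = params$c1, c2 = params$c2, pt = params$pt) {
  n <- length(state$ye1)
  if (any(!is.finite(state$ve)) || any(!is.finite(state$e_rate))) {
    bad <- which(!is.finite(state$ve) | !is.finite(state$e_rate))
    stop("simulation diverged: non-finite state in region(s) ",
         paste(bad, collapse = ", "))
  }
  dt <- 1 / params$sample_rate
  fe <- .filter_coef(params$he_decay, dt); fe2 <- .filter_coef(params$he_rise, dt)
  fi <- .filter_coef(params$hi_decay, dt); fi2 <- .filter_coef(params$hi_rise, dt)
  p_t <- pmax(params$thalamic_mean + params$thalamic_sd * noise_draw, 0)
  u_e <- rep_len(pt, n) * p_t + external_input
  u_i <- rep_len(c2, n) * state$i_rate
  u_c <- rep_len(c1, n) * state$e_rate
  state$ye1 <- fe$d * state$ye1 + fe$k * u_e
  state$ye2 <- fe2$d * state$ye2 + fe2$k * u_e
  state$yi1 <- fi$d * state$yi1 + fi$k * u_i
  state$yi2 <- fi2$d * state$yi2 + fi2$k * u_i
  state$yc1 <- fe$d * state$yc1 + fe$k * u_c
  state$yc2 <- fe2$d * state$yc2 + fe2$k * u_c
  state$ve <- params$he_gain * (state$ye1 - state$ye2) -
    params$hi_gain * (state$yi1 - state$yi2)
  state$vi <- params$he_gain * (state$yc1 - state$yc2)
  state$e_rate <- nmm_sigmoid(state$ve, params$sigmoid_e)
  state$i_rate <- nmm_sigmoid(state$vi, params$sigmoid_i)
  state
}

#' Simulate a single uncoupled neural mass
#'
#' Convenience driver for one mass under noisy thalamic drive; used for
#' calibration checks (the alpha peak of the uncoupled mass) and as the
#' reference trace for the decoupling identity of the network simulator.
#'
#' @param params an `nmm_params` object.
#' @param n_samples samples to record after the warm-up.
#' @param seed RNG seed for the thalamic noise stream.
#' @param warmup_samples discarded initial samples.
#' @return A list with `ve` and `e_rate` traces (length `n_samples`).
#' @export
simulate_mass <- function(params, n_samples, seed = 1L, warmup_samples = 1000L) {
  noise <- region_noise_stream(seed, 1L, n_samples + warmup_samples)
  st <- nmm_state(1L, params)
  total <- n_samples + warmup_samples
  ve <- numeric(n_samples); e <- numeric(n_samples)
  for (t in seq_len(total)) {
    st <- step_mass(st, params, external_input = 0, noise_draw = noise[t, 1L])
    if (t > warmup_samples) {
      ve[t - warmup_samples] <- st$ve
      e[t - warmup_samples] <- st$e_rate
    }
  }
  list(ve = ve, e_rate = e)
}

# Per-(seed, region) reproducible standard-normal stream, independent across
# regions, so that decoupled network runs match single-mass runs bit for bit.
region_noise_stream <- function(seed, n_regions, n_samples) {
  out <- matrix(0, n_samples, n_regions)
  for (i in seq_len(n_regions)) {
    rs <- .mix_seed(seed, i)
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(rs)
    out[, i] <- stats::rnorm(n_samples)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  out
}

# Deterministic integer mixing kept below 2^31.
.mix_seed <- function(seed, stream) {
  x <- (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
  as.integer(x)
}
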