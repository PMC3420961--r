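#' Simulation configuration
#'
#' @param coupling_strength global initial coupling S between masses (>= 0);
#'   overrides the value stored in the network when not `NULL`.
#' @param epoch_samples samples per analysis epoch (>= 256; default 4096,
#'   about 8.2 s at 500 Hz).
#' @param n_epochs epochs recorded per run.
#' @param warmup_samples discarded initial samples (default 2 s at 500 Hz).
#' @param seed master seed; per-run, per-region noise streams are derived
#'   from it deterministically.
#' @param record which traces to keep: any of `"ve"`, `"e_rate"`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(coupling_strength = NULL,
                              epoch_samples = 4096L,
                              n_epochs = 1L,
                              warmup_samples = 1000L,
                              seed = 1L,
                              record = c("ve", "e_rate")) {
  epoch_samples <- as.integer(epoch_samples)
  if (epoch_samples < 256L) stop("epoch_samples must be >= 256")
  if (!is.null(coupling_strength) && coupling_strength < 0)
    stop("coupling_strength must be >= 0")
  structure(list(coupling_strength = coupling_strength,
                 epoch_samples = epoch_samples,
                 n_epochs = as.integer(n_epochs),
                 warmup_samples = as.integer(warmup_samples),
                 seed = as.integer(seed),
                 record = match.arg(record, several.ok = TRUE)),
            class = "simulation_config")
}

# Internal vectorized multi-epoch driver. `coupling` is the (possibly
# degraded) matrix gain * S_ij; c1/c2/pt are per-region vectors. The noise
# matrix has one column per region. Returns traces plus the final state and
# delay buffer so that degeneration runs can continue where they left off.
.run_epochs <- function(params, coupling, c1, c2, pt, noise,
                        n_record, state = NULL, delay_buf = NULL,
                        delay = 1L) {
  n <- ncol(noise)
  total <- nrow(noise)
  warm <- total - n_record
  if (is.null(state)) state <- nmm_state(n, params)
  if (is.null(delay_buf))
    delay_buf <- matrix(state$e_rate, nrow = delay, ncol = n, byrow = TRUE)
  dt <- 1 / params$sample_rate
  fe <- .filter_coef(params$he_decay, dt); fe2 <- .filter_coef(params$he_rise, dt)
  fi <- .filter_coef(params$hi_decay, dt); fi2 <- .filter_coef(params$hi_rise, dt)
  se <- params$sigmoid_e; si <- params$sigmoid_i
  qe <- se[["max_rate"]]; the <- se[["threshold"]]; ste <- se[["steepness"]]
  qi <- si[["max_rate"]]; thi <- si[["threshold"]]; sti <- si[["steepness"]]
  ye1 <- state$ye1; ye2 <- state$ye2; yi1 <- state$yi1; yi2 <- state$yi2
  yc1 <- state$yc1; yc2 <- state$yc2
  e_rate <- state$e_rate; i_rate <- state$i_rate
  ve_tr <- matrix(0, n_record, n); e_tr <- matrix(0, n_record, n)
  buf_ptr <- 1L
  coupled <- any(coupling != 0)
  for (t in seq_len(total)) {
    e_delayed <- delay_buf[buf_ptr, ]
    u_ext <- if (coupled) as.vector(coupling %*% e_delayed) else numeric(n)
    p_t <- pmax(params$thalamic_mean + params$thalamic_sd * noise[t, ], 0)
    u_e <- pt * p_t + u_ext
    u_i <- c2 * i_rate
    u_c <- c1 * e_rate
    ye1 <- fe$d * ye1 + fe$k * u_e;  ye2 <- fe2$d * ye2 + fe2$k * u_e
    yi1 <- fi$d * yi1 + fi$k * u_i;  yi2 <- fi2$d * yi2 + fi2$k * u_i
    yc1 <- fe$d * yc1 + fe$k * u_c;  yc2 <- fe2$d * yc2 + fe2$k * u_c
    ve <- params$he_gain * (ye1 - ye2) - params$hi_gain * (yi1 - yi2)
    vi <- params$he_gain * (yc1 - yc2)
    e_rate <- qe / (1 + exp(-ste * (ve - the)))
    i_rate <- qi / (1 + exp(-sti * (vi - thi)))
    if (anyNA(ve) || any(!is.finite(ve)))
      stop("simulation diverged at sample ", t, " in region(s) ",
           paste(which(!is.finite(ve)), collapse = ", "))
    delay_buf[buf_ptr, ] <- e_rate
    buf_ptr <- if (buf_ptr == delay) 1L else buf_ptr + 1L
    if (t > warm) { ve_tr[t - warm, ] <- ve; e_tr[t - warm, ] <- e_rate }
  }
  state$ye1 <- ye1; state$ye2 <- ye2; state$yi1 <- yi1; state$yi2 <- yi2
  state$yc1 <- yc1; state$yc2 <- yc2; state$e_rate <- e_rate; state$i_rate <- i_rate
  state$ve <- ve; state$vi <- vi
  list(ve = ve_tr, e_rate = e_tr, state = state, delay_buf = delay_buf,
       buf_ptr = buf_ptr)
}

#' Advance a whole coupled network by one sample
#'
#' Thin per-sample interface over the lockstep update: each mass receives the
#' coupling-weighted, gain-scaled sum of the other masses' excitatory pulse
#' densities from `delay_samples` steps back, plus its own thalamic noise,
#' and advances via the single-mass update rule.
#'
#' @param state an `nmm_state` for all regions.
#' @param network a `structural_network`.
#' @param delay_buffer matrix (delay x regions) holding past excitatory pulse
#'   densities, oldest row first.
#' @param params an `nmm_params`.
#' @param noise_draw per-region standard-normal draws for this sample.
#' @param c1,c2,pt optional per-region degraded coupling vectors.
#' @return List with the advanced `state` and rotated `delay_buffer`.
#' @export
step_network <- function(state, network, delay_buffer, params, noise_draw,
                         c1 = params$c1, c2 = params$c2, pt = params$pt) {
  n <- length(network$labels)
  if (nrow(delay_buffer) < network$delay_samples)
    stop("delay buffer shorter than the configured delay")
  e_delayed <- delay_buffer[1L, ]
  u_ext <- as.vector(network$gain * network$coupling %*% e_delayed)
  state <- step_mass(state, params, external_input = u_ext,
                     noise_draw = noise_draw, c1 = c1, c2 = c2, pt = pt)
  delay_buffer <- rbind(delay_buffer[-1L, , drop = FALSE],
                        matrix(state$e_rate, nrow = 1L))
  list(state = state, delay_buffer = delay_buffer)
}

#' Simulate one run of the coupled network
#'
#' Runs all masses in lockstep with one-sample-delayed (configurable),
#' gain-scaled excitatory inter-mass coupling, discards the warm-up, and
#' records per-region membrane-potential and spike-density traces for each
#' epoch.
#'
#' @param network a `structural_network`.
#' @param params an `nmm_params`.
#' @param config a `simulation_config`; `config$seed` fixes the per-region
#'   thalamic noise streams.
#' @return An object of class `simulation_record`: list with `ve` and
#'   `e_rate` (lists of epoch matrices, samples x regions), `labels`,
#'   `sample_rate`, and a per-region summary data.frame (mean spike density
#'   and total power per epoch).
#' @export
simulate_network <- function(network, params = nmm_params(),
                             config = simulation_config()) {
  n <- length(network$labels)
  S <- if (!is.null(config$coupling_strength)) config$coupling_strength
       else network$coupling_strength
  coupling <- network$gain * S * network$adjacency
  total <- config$warmup_samples + config$epoch_samples * config$n_epochs
  noise <- region_noise_stream(config$seed, n, total)
  res <- .run_epochs(params, coupling,
                     c1 = rep(params$c1, n), c2 = rep(params$c2, n),
                     pt = rep(params$pt, n), noise = noise,
                     n_record = config$epoch_samples * config$n_epochs,
                     delay = network$delay_samples)
  epochs_ve <- epochs_e <- vector("list", config$n_epochs)
  for (ep in seq_len(config$n_epochs)) {
    idx <- ((ep - 1L) * config$epoch_samples + 1L):(ep * config$epoch_samples)
    epochs_ve[[ep]] <- res$ve[idx, , drop = FALSE]
    epochs_e[[ep]] <- res$e_rate[idx, , drop = FALSE]
  }
  summary <- do.call(rbind, lapply(seq_len(config$n_epochs), function(ep) {
    data.frame(epoch = ep, region = network$labels,
               mean_spike_density = colMeans(epochs_e[[ep]]),
               total_power = apply(epochs_ve[[ep]], 2, function(x)
                 total_power(power_spectrum(x, params$sample_rate))),
               row.names = NULL)
  }))
  structure(list(ve = if ("ve" %in% config$record) epochs_ve else NULL,
                 e_rate = if ("e_rate" %in% config$record) epochs_e else NULL,
                 labels = network$labels,
                 sample_rate = params$sample_rate,
                 coupling_strength = S,
                 seed = config$seed,
                 summary = summary),
            class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  eps <- length(x$ve %||% x$e_rate)
  cat(sprintf("Simulation record: %d regions, %d epoch(s), S = %g, seed %d\n",
              length(x$labels), eps, x$coupling_strength, x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an ensemble of independent network simulations
#'
#' Repeats [simulate_network()] `n_runs` times with per-run seeds derived
#' deterministically from the master seed, and aggregates the per-region
#' summaries (mean and standard deviation across runs).
#'
#' @param network a `structural_network`.
#' @param params an `nmm_params`.
#' @param config a `simulation_config`; its `seed` is the master seed.
#' @param n_runs number of runs (default 20).
#' @param keep_traces keep the full per-run trace matrices (memory-heavy);
#'   by default only summaries and the last run's traces are retained.
#' @return An object of class `simulation_ensemble`: list with `runs` (the
#'   per-run records if `keep_traces`, else `NULL`), `summary` (per-region
#'   data.frame with across-run mean and sd of spike density and total
#'   power), `per_run` (long data.frame), `n_runs`, `labels`.
#' @export
run_ensemble <- function(network, params = nmm_params(),
                         config = simulation_config(), n_runs = 20L,
                         keep_traces = FALSE) {
  per_run <- vector("list", n_runs)
  runs <- if (keep_traces) vector("list", n_runs) else NULL
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- .mix_seed(config$seed, 1000L + r)
    rec <- simulate_network(network, params, cfg)
    s <- rec$summary
    s$run <- r
    per_run[[r]] <- s
    if (keep_traces) runs[[r]] <- rec
  }
  long <- do.call(rbind, per_run)
  agg <- stats::aggregate(cbind(mean_spike_density, total_power) ~ region,
                          data = long, FUN = mean)
  sds <- stats::aggregate(cbind(mean_spike_density, total_power) ~ region,
                          data = long, FUN = stats::sd)
  names(agg)[2:3] <- c("mean_spike_density", "total_power")
  agg$sd_spike_density <- sds$mean_spike_density[match(agg$region, sds$region)]
  agg$sd_total_power <- sds$total_power[match(agg$region, sds$region)]
  # restore network region order
  agg <- agg[match(network$labels, agg$region), ]
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg, per_run = long,
                 n_runs = n_runs, labels = network$labels,
                 coupling_strength = if (!is.null(config$coupling_strength))
                   config$coupling_strength else network$coupling_strength,
                 seed = config$seed),
            class = "simulation_ensemble")
}

#' @export
print.simulation_ensemble <- function(x, ...) {
  cat(sprintf("Simulation ensemble: %d runs x %d regions, S = %g\n",
              x$n_runs, length(x$labels), x$coupling_strength))
  invisible(x)
}
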