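#' Loss factor from recent peak spike density
#'
#' Maps the highest recent spike density of a region (`max_act`, spikes/s)
#' to a multiplicative loss factor applied to its couplings. The default
#' exponential form `exp(-loss_rate * max_act)` is 1 at zero activity,
#' strictly decreasing in activity and in the loss rate, and always in
#' (0, 1]. The alternative linear form `max(0, 1 - loss_rate * max_act)`
#' can reach exactly 0 under extreme activity.
#'
#' @param max_act non-negative spike density (spikes/s); vectorized.
#' @param loss_rate rate constant rho (> 0), per update and per spikes/s.
#' @param form `"exponential"` (default) or `"linear"`.
#' @return Loss factor(s) in \[0, 1\] (strictly positive for the
#'   exponential form).
#' @export
#' @examples
#' compute_loss(0, 1e-4)    # 1: no activity, no damage
#' compute_loss(400, 1e-4)  # < 1
compute_loss <- function(max_act, loss_rate, form = c("exponential", "linear")) {
  form <- match.arg(form)
  if (any(max_act < 0)) stop("max_act must be non-negative")
  if (loss_rate <= 0) stop("loss_rate must be > 0")
  switch(form,
         exponential = exp(-loss_rate * max_act),
         linear = pmax(0, 1 - loss_rate * max_act))
}

#' Degeneration bookkeeping state
#'
#' Holds the quantities degraded by the activity-dependent rule: the
#' per-region intra-mass couplings (`c1`, `c2`), the thalamic input gain
#' (`pt`), and the inter-mass coupling matrix, together with the original
#' node strengths and an update counter.
#'
#' @param network a `structural_network`.
#' @param params an `nmm_params` providing the baseline `c1`, `c2`, `pt`.
#' @param loss_rate rho for [compute_loss()].
#' @param loss_form `"exponential"` or `"linear"`.
#' @return An object of class `degeneration_state`.
#' @export
degeneration_state <- function(network, params, loss_rate = 1.5e-5,
                               loss_form = "exponential") {
  n <- length(network$labels)
  coupling <- network$gain * network$coupling
  structure(list(
    labels = network$labels,
    c1 = rep(params$c1, n), c2 = rep(params$c2, n), pt = rep(params$pt, n),
    coupling = coupling,
    original_strength = rowSums(coupling),
    loss_rate = loss_rate, loss_form = loss_form,
    update = 0L,
    last_loss = rep(1, n), last_max_act = rep(NA_real_, n)
  ), class = "degeneration_state")
}

#' @export
print.degeneration_state <- function(x, ...) {
  cat(sprintf("Degeneration state: update %d, mean normalized node strength %.3f\n",
              x$update, mean(normalized_node_strength(x))))
  invisible(x)
}

#' Peak spike density over the activity buffer
#'
#' `max_act` per region: the maximum excitatory pulse density over the last
#' `buffer_steps` model samples (default 20).
#'
#' @param e_trace samples x regions spike-density matrix for the most recent
#'   epoch.
#' @param buffer_steps buffer length in samples.
#' @return Numeric vector of per-region maxima.
#' @export
max_activity <- function(e_trace, buffer_steps = 20L) {
  if (nrow(e_trace) < buffer_steps)
    stop("activity buffer not filled: need at least ", buffer_steps, " samples")
  tail_rows <- e_trace[(nrow(e_trace) - buffer_steps + 1L):nrow(e_trace), , drop = FALSE]
  apply(tail_rows, 2, max)
}

#' Apply one activity-dependent degeneration update
#'
#' For each region i, computes `loss_i` from its recent peak spike density
#' and multiplies `c1_i`, `c2_i`, `pt_i` and every coupling incident to i by
#' `loss_i` (so edge (i, j) shrinks by `loss_i * loss_j`, preserving
#' symmetry). All degraded quantities are non-increasing, strictly
#' decreasing wherever activity is positive.
#'
#' @param deg a `degeneration_state`.
#' @param max_act per-region peak spike densities (from [max_activity()]).
#' @return The updated `degeneration_state`.
#' @export
apply_add <- function(deg, max_act) {
  if (length(max_act) != length(deg$c1))
    stop("max_act length does not match region count")
  loss <- compute_loss(max_act, deg$loss_rate, deg$loss_form)
  deg$c1 <- deg$c1 * loss
  deg$c2 <- deg$c2 * loss
  deg$pt <- deg$pt * loss
  deg$coupling <- deg$coupling * outer(loss, loss)
  deg$update <- deg$update + 1L
  deg$last_loss <- loss
  deg$last_max_act <- max_act
  deg
}

#' Apply one random (activity-independent) degeneration update
#'
#' The control condition: the same multiplicative machinery as the
#' activity-dependent rule, but with one common loss factor for every
#' region, so damage is spatially uniform and normalized node strength shows
#' no hub/non-hub difference.
#'
#' @param deg a `degeneration_state`.
#' @param reference_loss common loss factor in (0, 1\]; when `NULL`, derived
#'   from the region-mean of `max_act` so total damage tracks a matched
#'   activity-dependent run.
#' @param max_act optional per-region peak spike densities used only to
#'   derive the default factor.
#' @return The updated `degeneration_state`.
#' @export
apply_rd <- function(deg, reference_loss = NULL, max_act = NULL) {
  if (is.null(reference_loss)) {
    if (is.null(max_act)) stop("supply reference_loss or max_act")
    reference_loss <- compute_loss(mean(max_act), deg$loss_rate, deg$loss_form)
  }
  if (reference_loss <= 0 || reference_loss > 1)
    stop("reference_loss must be in (0, 1]")
  n <- length(deg$c1)
  loss <- rep(reference_loss, n)
  deg$c1 <- deg$c1 * loss
  deg$c2 <- deg$c2 * loss
  deg$pt <- deg$pt * loss
  deg$coupling <- deg$coupling * outer(loss, loss)
  deg$update <- deg$update + 1L
  deg$last_loss <- loss
  deg$last_max_act <- if (is.null(max_act)) rep(NA_real_, n) else max_act
  deg
}

#' Normalized node strength
#'
#' Ratio of each region's current summed coupling strength to its original
#' value: 1 at baseline by definition, non-increasing under degeneration.
#'
#' @param deg a `degeneration_state`.
#' @return Named numeric vector in \[0, 1\].
#' @export
normalized_node_strength <- function(deg) {
  s <- rowSums(deg$coupling) / deg$original_strength
  names(s) <- deg$labels
  s
}

#' Run a degeneration trajectory
#'
#' Alternates simulation epochs with degeneration updates: each update uses
#' the peak spike density over the final `buffer_steps` samples of the
#' preceding epoch (the activity buffer), then scales the couplings. The
#' simulator state carries over between epochs, so the trajectory is one
#' continuous recording. Per update, per-region spike density, total power,
#' node strength, loss and `max_act` are recorded; full traces can be kept
#' at selected updates for connectivity analysis.
#'
#' @param network a `structural_network`.
#' @param params an `nmm_params`.
#' @param mode `"add"` (activity-dependent) or `"rd"` (uniform control).
#' @param n_updates number of degeneration updates.
#' @param epoch_samples samples simulated per update.
#' @param seed RNG seed for the thalamic streams.
#' @param loss_rate,loss_form passed to [degeneration_state()].
#' @param rd_reference fixed common loss for `"rd"` mode; `NULL` derives it
#'   from the mean activity each update.
#' @param warmup_samples initial samples before the first epoch.
#' @param buffer_steps activity-buffer length in samples (default 20).
#' @param keep_trace_updates integer vector of update indices (0 = baseline
#'   epoch) at which the full ve/spike traces are retained.
#' @return An object of class `degeneration_record`: list with `trajectory`
#'   (long data.frame: update, region, spike_density, total_power,
#'   node_strength, normalized_node_strength, max_act, loss, c1, c2, pt),
#'   `traces` (named list of kept epochs), `mode`, `labels`.
#' @export
run_degeneration <- function(network, params = nmm_params(),
                             mode = c("add", "rd"),
                             n_updates = 100L,
                             epoch_samples = 4096L,
                             seed = 1L,
                             loss_rate = 1.5e-5, loss_form = "exponential",
                             rd_reference = NULL,
                             warmup_samples = 1000L,
                             buffer_steps = 20L,
                             keep_trace_updates = integer(0)) {
  mode <- match.arg(mode)
  n <- length(network$labels)
  deg <- degeneration_state(network, params, loss_rate, loss_form)
  total0 <- warmup_samples + epoch_samples
  state <- NULL; delay_buf <- NULL
  rows <- vector("list", n_updates + 1L)
  traces <- list()
  for (u in 0:n_updates) {
    noise <- region_noise_stream(.mix_seed(seed, 5000L + u), n,
                                 if (u == 0) total0 else epoch_samples)
    res <- .run_epochs(params, deg$coupling, c1 = deg$c1, c2 = deg$c2,
                       pt = deg$pt, noise = noise,
                       n_record = epoch_samples,
                       state = state, delay_buf = delay_buf,
                       delay = network$delay_samples)
    state <- res$state; delay_buf <- res$delay_buf
    tp <- apply(res$ve, 2, function(x)
      total_power(power_spectrum(x, params$sample_rate)))
    ma <- max_activity(res$e_rate, buffer_steps)
    rows[[u + 1L]] <- data.frame(
      update = u, region = deg$labels,
      spike_density = colMeans(res$e_rate),
      total_power = tp,
      node_strength = rowSums(deg$coupling),
      normalized_node_strength = unname(normalized_node_strength(deg)),
      max_act = ma,
      loss = deg$last_loss,
      c1 = deg$c1, c2 = deg$c2, pt = deg$pt,
      row.names = NULL)
    if (u %in% keep_trace_updates)
      traces[[as.character(u)]] <- list(ve = res$ve, e_rate = res$e_rate)
    if (u < n_updates) {
      deg <- if (mode == "add") apply_add(deg, ma)
             else apply_rd(deg, reference_loss = rd_reference, max_act = ma)
    }
  }
  structure(list(trajectory = do.call(rbind, rows), traces = traces,
                 mode = mode, labels = deg$labels, loss_rate = loss_rate,
                 loss_form = loss_form, seed = seed,
                 final_state = deg),
            class = "degeneration_record")
}

#' @export
print.degeneration_record <- function(x, ...) {
  cat(sprintf("Degeneration record (%s): %d regions, %d updates\n",
              toupper(x$mode), length(x$labels), max(x$trajectory$update)))
  invisible(x)
}
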