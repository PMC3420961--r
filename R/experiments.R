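#' Hub versus non-hub contrast
#'
#' Welch two-sample comparison of a per-region metric between hubs and
#' non-hubs.
#'
#' @param values named numeric vector (names = region labels) or plain
#'   vector in partition order.
#' @param partition a `hub_partition`.
#' @param alternative `"greater"` (hubs > non-hubs), `"less"`, or
#'   `"two.sided"`.
#' @return List with group means, `difference`, Welch `statistic`, `df`,
#'   `p_value`, and Cohen's `d`.
#' @export
hub_contrast <- function(values, partition, alternative = "greater") {
  if (is.null(names(values))) names(values) <- names(partition$bin)
  hv <- values[partition$hubs]; nv <- values[partition$non_hubs]
  if (length(hv) < 2 || length(nv) < 2) stop("need >= 2 regions per group")
  if (stats::sd(hv) == 0 && stats::sd(nv) == 0) {
    return(list(hub_mean = mean(hv), non_hub_mean = mean(nv),
                difference = mean(hv) - mean(nv), statistic = 0,
                df = NA_real_, p_value = 1, cohens_d = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(hv, nv, alternative = alternative, var.equal = FALSE)
  sp <- sqrt((stats::var(hv) * (length(hv) - 1) + stats::var(nv) * (length(nv) - 1)) /
               (length(hv) + length(nv) - 2))
  list(hub_mean = mean(hv), non_hub_mean = mean(nv),
       difference = mean(hv) - mean(nv),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       cohens_d = if (sp > 0) (mean(hv) - mean(nv)) / sp else 0,
       degenerate = FALSE)
}

#' Binned per-region summary
#'
#' Means and standard deviations of a per-region metric within the
#' ascending-degree bins of a hub partition (the standard six-bin display).
#'
#' @param values named per-region numeric vector.
#' @param partition a `hub_partition`.
#' @return data.frame with bin, n, mean_degree, mean, sd, sem.
#' @export
binned_summary <- function(values, partition) {
  if (is.null(names(values))) names(values) <- names(partition$bin)
  do.call(rbind, lapply(seq_along(partition$bins), function(b) {
    regs <- partition$bins[[b]]
    v <- values[regs]
    data.frame(bin = b, n = length(regs),
               mean_degree = mean(partition$degree[regs]),
               mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
}

#' Baseline connectivity-activity experiment
#'
#' For each coupling strength S, runs an ensemble of independent network
#' simulations, averages per-region spike density, total power, and alpha
#' peak frequency over runs (optionally adding broadband functional degree
#' from the synchronization likelihood), classifies hubs from structural
#' degree, and reports Pearson correlations of structural degree against the
#' activity measures together with hub/non-hub contrasts.
#'
#' @param network a `structural_network`.
#' @param S_values coupling strengths to test (default `c(1.0, 1.5, 2.0)`).
#' @param n_runs runs per ensemble (default 20).
#' @param seed master seed.
#' @param params an `nmm_params`.
#' @param epoch_samples samples per run after warm-up.
#' @param warmup_samples discarded initial samples.
#' @param compute_sl also compute broadband (0.5-45 Hz) functional degree
#'   (adds substantial runtime).
#' @param sl_band band for the functional degree when `compute_sl`.
#' @return An object of class `experiment1_report`: list with `per_region`
#'   (one data.frame per S), `correlations` (data.frame: S, metric, r, n),
#'   `hub_tests`, `binned`, `partition`.
#' @export
experiment1 <- function(network, S_values = c(1.0, 1.5, 2.0), n_runs = 20L,
                        seed = 42L, params = nmm_params(),
                        epoch_samples = 4096L, warmup_samples = 1000L,
                        compute_sl = FALSE, sl_band = c(0.5, 45)) {
  partition <- classify_hubs(network)
  k <- structural_degree(network)
  per_region <- list(); cors <- list(); hubs <- list(); binned <- list()
  for (S in S_values) {
    acc_sp <- acc_pw <- acc_ap <- matrix(0, n_runs, length(k))
    acc_fd <- if (compute_sl) matrix(0, n_runs, length(k)) else NULL
    for (r in seq_len(n_runs)) {
      cfg <- simulation_config(coupling_strength = S,
                               epoch_samples = epoch_samples,
                               warmup_samples = warmup_samples,
                               seed = .mix_seed(seed, 1000L + r))
      rec <- simulate_network(network, params, cfg)
      ve <- rec$ve[[1]]
      acc_sp[r, ] <- colMeans(rec$e_rate[[1]])
      psds <- apply(ve, 2, power_spectrum, sample_rate = params$sample_rate,
                    simplify = FALSE)
      acc_pw[r, ] <- vapply(psds, total_power, numeric(1))
      acc_ap[r, ] <- vapply(psds, alpha_peak, numeric(1))
      if (compute_sl) {
        fn <- functional_network(ve, band = sl_band,
                                 sample_rate = params$sample_rate,
                                 labels = network$labels)
        acc_fd[r, ] <- fn$functional_degree
      }
    }
    tab <- data.frame(region = network$labels,
                      structural_degree = as.integer(k),
                      spike_density = colMeans(acc_sp),
                      sd_spike_density = apply(acc_sp, 2, stats::sd),
                      total_power = colMeans(acc_pw),
                      sd_total_power = apply(acc_pw, 2, stats::sd),
                      alpha_peak_hz = colMeans(acc_ap),
                      row.names = NULL)
    if (compute_sl) {
      tab$functional_degree <- colMeans(acc_fd)
      tab$sd_functional_degree <- apply(acc_fd, 2, stats::sd)
    }
    key <- sprintf("S=%g", S)
    per_region[[key]] <- tab
    cr <- data.frame(
      S = S,
      metric = c("total_power", "spike_density", "alpha_peak_hz",
                 if (compute_sl) "functional_degree"),
      r = c(pearson(k, tab$total_power),
            pearson(k, tab$spike_density),
            pearson(k, tab$alpha_peak_hz),
            if (compute_sl) pearson(k, tab$functional_degree)),
      n = length(k))
    cors[[key]] <- cr
    hubs[[key]] <- list(
      total_power = hub_contrast(stats::setNames(tab$total_power, tab$region), partition),
      spike_density = hub_contrast(stats::setNames(tab$spike_density, tab$region), partition))
    binned[[key]] <- list(
      total_power = binned_summary(stats::setNames(tab$total_power, tab$region), partition),
      spike_density = binned_summary(stats::setNames(tab$spike_density, tab$region), partition))
  }
  structure(list(per_region = per_region,
                 correlations = do.call(rbind, c(cors, list(make.row.names = FALSE))),
                 hub_tests = hubs, binned = binned, partition = partition,
                 n_runs = n_runs, seed = seed),
            class = "experiment1_report")
}

#' @export
print.experiment1_report <- function(x, ...) {
  cat("Baseline connectivity-activity experiment\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Degeneration experiment: trajectories under ADD or RD
#'
#' Runs `n_runs` independent degeneration trajectories, then aggregates
#' hub/non-hub mean time courses of normalized node strength, spike density
#' and total power, with hub-vs-non-hub contrasts at each update. At
#' selected updates, band-limited functional connectivity (mean
#' synchronization likelihood) and graph metrics of the degree-thresholded
#' functional graph (Cp, Lp, Newman Q) are computed from the retained
#' traces.
#'
#' @param network a `structural_network`.
#' @param mode `"add"` or `"rd"`.
#' @param n_updates degeneration updates per run.
#' @param S coupling strength (default 1.5).
#' @param n_runs independent runs (default 20).
#' @param seed master seed.
#' @param params an `nmm_params`.
#' @param epoch_samples samples per update epoch.
#' @param loss_rate,loss_form degeneration constants.
#' @param metric_updates updates at which SL/graph metrics are computed
#'   (`NULL` for none; default: about 8 evenly spaced points).
#' @param band band for the functional analysis (default lower alpha 8-10 Hz).
#' @param target_mean_degree threshold density for the functional graph.
#' @return An object of class `experiment2_report`: list with `timecourse`
#'   (data.frame: update, group, metric, mean, sd, sem), `contrasts`
#'   (normalized node strength per update), `network_metrics` (data.frame
#'   per metric update: mean SL, cp, lp, q), `runs` (trajectories).
#' @export
experiment2 <- function(network, mode = c("add", "rd"), n_updates = 60L,
                        S = 1.5, n_runs = 20L, seed = 42L,
                        params = nmm_params(),
                        epoch_samples = 4096L,
                        loss_rate = 1.5e-5, loss_form = "exponential",
                        metric_updates = NULL,
                        band = c(8, 10), target_mean_degree = 8) {
  mode <- match.arg(mode)
  net <- network
  net$coupling <- S * net$adjacency
  net$coupling_strength <- S
  if (is.null(metric_updates))
    metric_updates <- unique(round(seq(0, n_updates, length.out = 8)))
  partition <- classify_hubs(network)
  hub_idx <- match(partition$hubs, network$labels)
  non_idx <- match(partition$non_hubs, network$labels)
  runs <- vector("list", n_runs)
  net_metrics <- list()
  for (r in seq_len(n_runs)) {
    rec <- run_degeneration(net, params, mode = mode, n_updates = n_updates,
                            epoch_samples = epoch_samples,
                            seed = .mix_seed(seed, 3000L + r),
                            loss_rate = loss_rate, loss_form = loss_form,
                            keep_trace_updates = metric_updates)
    runs[[r]] <- rec$trajectory
    for (u in names(rec$traces)) {
      ve <- rec$traces[[u]]$ve
      fn <- tryCatch(
        functional_network(ve, band = band, sample_rate = params$sample_rate,
                           labels = network$labels),
        error = function(e) NULL)
      if (is.null(fn)) next
      g <- threshold_to_degree(fn$sl_matrix, target_mean_degree, on_short = "warn")
      cp_lp <- clustering_and_path(g)
      mod <- modularity_annealing(g, seed = .mix_seed(seed, 77L + as.integer(u)))
      sl_off <- fn$sl_matrix[upper.tri(fn$sl_matrix)]
      net_metrics[[length(net_metrics) + 1L]] <- data.frame(
        run = r, update = as.integer(u),
        mean_sl = mean(sl_off),
        mean_sl_hub = mean(fn$sl_matrix[hub_idx, ][, -1][fn$sl_matrix[hub_idx, ] > 0]),
        cp = cp_lp$cp, lp = cp_lp$lp, q = mod$q)
    }
  }
  long <- do.call(rbind, lapply(seq_len(n_runs), function(r)
    cbind(runs[[r]], run = r)))
  long$group <- ifelse(long$region %in% partition$hubs, "hub", "non_hub")
  agg <- stats::aggregate(
    cbind(spike_density, total_power, normalized_node_strength) ~ update + group,
    data = long, FUN = mean)
  sds <- stats::aggregate(
    cbind(spike_density, total_power, normalized_node_strength) ~ update + group,
    data = long, FUN = stats::sd)
  tc <- merge(agg, sds, by = c("update", "group"), suffixes = c("", "_sd"))
  tc <- tc[order(tc$update, tc$group), ]
  rownames(tc) <- NULL
  contrasts <- do.call(rbind, lapply(sort(unique(long$update)), function(u) {
    sub <- long[long$update == u, ]
    m <- stats::aggregate(normalized_node_strength ~ region, sub, mean)
    v <- stats::setNames(m$normalized_node_strength, m$region)
    hc <- hub_contrast(v, partition, alternative = "less")
    data.frame(update = u, hub_mean = hc$hub_mean, non_hub_mean = hc$non_hub_mean,
               difference = hc$difference, p_value = hc$p_value)
  }))
  structure(list(timecourse = tc, contrasts = contrasts,
                 network_metrics = if (length(net_metrics))
                   do.call(rbind, net_metrics) else NULL,
                 runs = long, partition = partition, mode = mode,
                 n_runs = n_runs, seed = seed),
            class = "experiment2_report")
}

#' @export
print.experiment2_report <- function(x, ...) {
  cat(sprintf("Degeneration experiment (%s): %d runs, %d updates\n",
              toupper(x$mode), x$n_runs, max(x$timecourse$update)))
  invisible(x)
}
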