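#' Load a run configuration file
#'
#' Reads a single YAML or JSON document holding the tunable constants of
#' every layer — neural mass constants (`nmm:`), simulation settings
#' (`simulation:`), degeneration settings (`degeneration:`), and
#' synchronization-likelihood settings (`sl:`) — and returns ready-to-use
#' objects. Any key left out keeps its package default; unknown keys raise
#' an error naming the offender. See
#' `system.file("extdata", "default_config.yaml", package = "addnet")` for a
#' fully commented example.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` (an [nmm_params()] object),
#'   `simulation` (a [simulation_config()]), `degeneration` (plain list:
#'   mode, loss_rate, loss_form, n_updates, rd_reference), and `sl` (plain
#'   list of overrides for [sl_params()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("nmm", "simulation", "degeneration", "sl")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config section(s): ", paste(extra, collapse = ", "))

  nm <- raw$nmm %||% list()
  nmm_ok <- names(formals(nmm_params))
  bad <- setdiff(names(nm), nmm_ok)
  if (length(bad) > 0)
    stop("unknown nmm key(s): ", paste(bad, collapse = ", "))
  for (f in c("sigmoid_e", "sigmoid_i"))
    if (!is.null(nm[[f]])) nm[[f]] <- unlist(nm[[f]])
  params <- do.call(nmm_params, nm)

  sc <- raw$simulation %||% list()
  sim_ok <- names(formals(simulation_config))
  n_runs <- sc$n_runs
  sc$n_runs <- NULL
  bad <- setdiff(names(sc), sim_ok)
  if (length(bad) > 0)
    stop("unknown simulation key(s): ", paste(bad, collapse = ", "))
  sim <- do.call(simulation_config, sc)

  dg <- raw$degeneration %||% list()
  dg_ok <- c("mode", "loss_rate", "loss_form", "n_updates", "rd_reference",
             "buffer_steps")
  bad <- setdiff(names(dg), dg_ok)
  if (length(bad) > 0)
    stop("unknown degeneration key(s): ", paste(bad, collapse = ", "))

  sl <- raw$sl %||% list()
  sl_ok <- setdiff(names(formals(sl_params)), "sample_rate")
  bad <- setdiff(names(sl), sl_ok)
  if (length(bad) > 0)
    stop("unknown sl key(s): ", paste(bad, collapse = ", "))

  list(params = params, simulation = sim, n_runs = n_runs,
       degeneration = dg, sl = sl)
}

#' Export simulation traces as delimited text
#'
#' Writes each recorded epoch of a simulation record as a tab-separated
#' matrix (samples x regions, with region names as header), a `summary.csv`
#' with the per-region epoch summaries, and a `meta.json` sidecar describing
#' shape, sample rate and seed.
#'
#' @param record a `simulation_record` from [simulate_network()].
#' @param dir output directory (created if missing).
#' @param what which traces to write: subset of `c("ve", "e_rate")`.
#' @return Invisibly, the paths written.
#' @export
write_record <- function(record, dir, what = c("ve", "e_rate")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (w in intersect(what, c("ve", "e_rate"))) {
    tr <- record[[w]]
    if (is.null(tr)) next
    for (ep in seq_along(tr)) {
      f <- file.path(dir, sprintf("%s_epoch%02d.tsv", w, ep))
      m <- tr[[ep]]
      colnames(m) <- record$labels
      utils::write.table(m, f, sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, f)
    }
  }
  sf <- file.path(dir, "summary.csv")
  utils::write.csv(record$summary, sf, row.names = FALSE)
  mf <- file.path(dir, "meta.json")
  meta <- list(n_regions = length(record$labels),
               epoch_samples = nrow(record$ve[[1]] %||% record$e_rate[[1]]),
               n_epochs = length(record$ve %||% record$e_rate),
               sample_rate = record$sample_rate,
               coupling_strength = record$coupling_strength,
               seed = record$seed,
               layout = "samples x regions, tab-separated, header = region labels")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, sf, mf))
}
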