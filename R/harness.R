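# vExperiment harness: assemble a Mouse (Body + vLiver + Dose), run seeded
# trials through the compiled engine, and aggregate Monte Carlo trials.

kind_names <- c("APAP", "G", "S", "ALT", "Marker")
event_names <- c("gsh_depleted", "mitigation", "leak_triggered",
                 "alt_scheduled", "alt_released", "necrosis_triggered",
                 "necrotic")
scope_names <- c("liver", "PP", "MZ", "PC")
amount_names <- c("apap_cell", "napqi", "mitoD", "nonMD", "ex_alt", "ex_apap")

#' Flatten a set of lobule graphs into a vLiver layout for the engine
#'
#' Concatenates the lobules' node and vHPC tables with global 0-based
#' indices, builds the downstream adjacency in compressed form (Central
#' Vein encoded as -1), and labels every node with the majority band of
#' its vHPCs (used to attribute extracellular compounds to bands).
#'
#' @param graphs list of `lobule_graph` objects with bands assigned.
#' @return a `liver_layout` list consumed by [run_trial()].
#' @export
build_liver <- function(graphs) {
  if (inherits(graphs, "lobule_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1)
  layer <- integer(0); nnv <- integer(0); ecc <- integer(0)
  node_band <- integer(0)
  eptr <- list(); eto <- integer(0); entry <- integer(0)
  node_of <- integer(0); band_of <- integer(0); zone <- numeric(0)
  node_edges <- list()
  offset <- 0L
  band_lv <- c(PP = 0L, MZ = 1L, PC = 2L, none = 3L)
  for (g in graphs) {
    if (is.null(g$vhpc$band)) stop("assign bands before building a liver")
    n <- nrow(g$nodes)
    layer <- c(layer, g$nodes$layer)
    nnv <- c(nnv, g$nodes$n_vhpc)
    ecc <- c(ecc, g$nodes$n_vec)
    # expand vHPC position rows into individual agents (rows are ordered by
    # node then position, so agents of one node are contiguous)
    v <- g$vhpc
    cnt <- v$count
    node_of <- c(node_of, rep.int(v$node - 1L + offset, cnt))
    band_of <- c(band_of, rep.int(band_lv[as.character(v$band)], cnt))
    zone <- c(zone, rep.int(v$zone, cnt))
    nb <- vapply(seq_len(n), function(nd) {
      bt <- tapply(cnt[v$node == nd], v$band[v$node == nd], sum, default = 0)
      band_lv[names(which.max(bt))]
    }, integer(1))
    node_band <- c(node_band, nb)
    ed <- g$edges
    internal <- ed[ed$from != 0L, , drop = FALSE]
    to0 <- ifelse(internal$to == n + 1L, -1L, internal$to - 1L + offset)
    from0 <- internal$from - 1L + offset
    node_edges <- c(node_edges,
                    lapply(seq_len(n), function(nd) to0[from0 == nd - 1L + offset]))
    entry <- c(entry, which(g$nodes$layer == 1L) - 1L + offset)
    offset <- offset + n
  }
  counts <- lengths(node_edges)
  structure(list(
    layer = layer, node_nvhpc = nnv, ec_cap = ecc, node_band = node_band,
    vhpc_off = c(0L, cumsum(nnv))[seq_along(nnv)],
    edge_ptr = as.integer(c(0L, cumsum(counts))),
    edge_to = as.integer(unlist(node_edges, use.names = FALSE)),
    entry_nodes = as.integer(entry),
    node_of = as.integer(node_of), band_of = as.integer(band_of),
    zone = zone, n_lobules = length(graphs)), class = "liver_layout")
}

#' Run one seeded simulation trial
#'
#' Samples a fresh vLiver (all Sinusoid Segment dimensions are Monte-Carlo
#' sampled at the start of each execution), doses the Mouse Body, and
#' executes `duration_cycles` one-second cycles.  Measurement agents
#' record Body amounts and cumulative per-band event counts at the end of
#' every cycle; per-band compound amounts are recorded every `thin`
#' cycles.  Runs are deterministic given the trial seed.  Internal object
#' ledgers are verified during the run; a violation aborts with the
#' offending cycle (a bug detector, not a warning).
#'
#' @param cfg a [vexperiment_config()].
#' @param trial_seed integer seed for this trial.
#' @param thin record per-band amount series every `thin` cycles.
#' @param check_every verify conservation ledgers every `check_every`
#'   cycles (0 disables).
#' @param return_state also return the final per-vHPC state.
#' @return an object of class `measurement_log`.
#' @export
run_trial <- function(cfg, trial_seed, thin = 60L, check_every = 600L,
                      return_state = FALSE) {
  stopifnot(inherits(cfg, "vexperiment_config"))
  graphs <- lapply(seq_len(cfg$n_lobules), function(i)
    assign_bands(sample_lobule_graph(cfg$lobule,
                                     seed = (trial_seed * 1009L + i) %% 2147483647L),
                 cfg$bands))
  liver <- build_liver(graphs)
  gradv <- list(
    p_metabolism = grad_value(cfg$gradients$p_metabolism, liver$zone),
    p_napqi = grad_value(cfg$gradients$p_napqi, liver$zone),
    gsh_threshold = grad_value(cfg$gradients$gsh_threshold, liver$zone),
    p_mitigate_mitod = grad_value(cfg$gradients$p_mitigate_mitod, liver$zone),
    p_mitigate_nonmd = grad_value(cfg$gradients$p_mitigate_nonmd, liver$zone),
    p_mito_fraction = cfg$gradients$p_mito_fraction)
  marker <- as.integer(round(cfg$marker_fraction * cfg$dose_objects))
  out <- .run_trial_cpp(unclass(liver), unclass(cfg$flow),
                        gradv, unclass(cfg$mechanism),
                        cfg$dose_objects, marker, cfg$duration_cycles,
                        as.numeric(trial_seed), as.integer(thin),
                        as.integer(check_every), return_state)
  colnames(out$body) <- kind_names
  colnames(out$events) <- paste(rep(scope_names, each = 7),
                                rep(event_names, 4), sep = ".")
  colnames(out$amounts) <- paste(rep(scope_names, each = 6),
                                 rep(amount_names, 4), sep = ".")
  out$n_vhpc <- length(liver$zone)
  out$n_per_band <- tabulate(liver$band_of + 1L, nbins = 4L)
  names(out$n_per_band) <- c("PP", "MZ", "PC", "none")
  out$trial_seed <- trial_seed
  out$cfg <- cfg
  class(out) <- "measurement_log"
  out
}

#' Run a vExperiment (a set of Monte Carlo trials)
#'
#' Trial `i` uses seed `master_seed + i`; measurements are averaged across
#' trials, with min/max/SD dispersion for the Body series.
#'
#' @param cfg a [vexperiment_config()].
#' @param thin,check_every passed to [run_trial()].
#' @param keep_trials retain the individual trial logs in the result.
#' @return an object of class `vexperiment_result` with `body_mean`,
#'   `body_min`, `body_max`, `body_sd` (cycle x kind matrices),
#'   `events_mean`, `amounts_mean`, pooled event-time vectors
#'   (`pc_trigger_cycles`, etc.) and metadata.
#' @export
run_vexperiment <- function(cfg, thin = 60L, check_every = 3600L,
                            keep_trials = FALSE) {
  stopifnot(inherits(cfg, "vexperiment_config"))
  seeds <- cfg$master_seed + seq_len(cfg$n_trials)
  trials <- lapply(seeds, function(s)
    run_trial(cfg, s, thin = thin, check_every = check_every))
  acc <- function(field) {
    arr <- simplify2array(lapply(trials, `[[`, field))
    list(mean = apply(arr, 1:2, mean), min = apply(arr, 1:2, min),
         max = apply(arr, 1:2, max), sd = apply(arr, 1:2, stats::sd))
  }
  body <- acc("body")
  ev <- simplify2array(lapply(trials, `[[`, "events"))
  amt <- simplify2array(lapply(trials, `[[`, "amounts"))
  pool <- function(field, band) {
    unlist(lapply(trials, function(tr) {
      x <- tr[[field]]
      x[x >= 0L & tr$band_of == band]
    }), use.names = FALSE)
  }
  res <- list(
    cfg = cfg, trial_seeds = seeds,
    body_mean = body$mean, body_min = body$min, body_max = body$max,
    body_sd = body$sd,
    events_mean = apply(ev, 1:2, mean),
    amounts_mean = apply(amt, 1:2, mean),
    amount_cycles = trials[[1]]$amount_cycles,
    pc_trigger_cycles = pool("trig_cycle", 2L),
    pc_leak_cycles = pool("leak_cycle", 2L),
    pc_necrotic_cycles = pool("necrotic_cycle", 2L),
    n_per_band = trials[[1]]$n_per_band,
    leak_frac = vapply(trials, function(tr) {
      pc <- tr$band_of == 2L
      sum(tr$leak_cycle[pc] >= 0L) / sum(pc)
    }, numeric(1)),
    trials = if (keep_trials) trials else NULL)
  class(res) <- "vexperiment_result"
  res
}

#' Extract the measurement record for one cycle
#'
#' Returns the end-of-cycle snapshot the measurement agents recorded:
#' Body amounts, cumulative per-scope event counts, and (at the nearest
#' recorded cycle) per-scope compound amounts.
#'
#' @param log a `measurement_log` from [run_trial()].
#' @param cycle cycle number (1-based row; cycle t is row t).
#' @return a list with `body`, `events` and `amounts`.
#' @export
measurement_at <- function(log, cycle) {
  stopifnot(inherits(log, "measurement_log"))
  if (cycle < 1L || cycle > nrow(log$body)) stop("cycle out of range")
  i <- which.min(abs(log$amount_cycles - (cycle - 1L)))
  list(body = log$body[cycle, ],
       events = log$events[cycle, ],
       amounts = log$amounts[i, ],
       amount_cycle = log$amount_cycles[i])
}

#' Fraction of band vHPCs Leakage-Triggered by a cycle
#'
#' @param x a `measurement_log` or `vexperiment_result`.
#' @param cycle cycle (1-second) cutoff, inclusive.
#' @param band one of `"PP"`, `"MZ"`, `"PC"`.
#' @return for a vExperiment, the mean across trials of the per-trial
#'   fraction; for a single trial, that trial's fraction.
#' @export
leak_triggered_fraction <- function(x, cycle, band = "PC") {
  b <- match(band, c("PP", "MZ", "PC")) - 1L
  frac1 <- function(tr) {
    inb <- tr$band_of == b
    sum(tr$leak_cycle[inb] >= 0L & tr$leak_cycle[inb] <= cycle) / sum(inb)
  }
  if (inherits(x, "measurement_log")) return(frac1(x))
  stopifnot(inherits(x, "vexperiment_result"))
  ev <- paste0(band, ".leak_triggered")
  # cumulative count at `cycle`, averaged across trials, over band size
  x$events_mean[cycle, ev] / x$n_per_band[band]
}

#' Median Necrosis-Trigger time within a band
#'
#' Pools Necrosis-Triggered event times across all trials of a
#' vExperiment and returns the median, in minutes post-Dose.
#'
#' @param res a `vexperiment_result`.
#' @param band band name (default `"PC"`).
#' @return median trigger time in minutes (NA if no events).
#' @export
necrosis_trigger_median_min <- function(res, band = "PC") {
  stopifnot(inherits(res, "vexperiment_result"))
  cyc <- switch(band, PC = res$pc_trigger_cycles,
                stop("pooled trigger times retained for the PC band only"))
  if (!length(cyc)) return(NA_real_)
  stats::median(cyc) / 60
}

#' @export
print.vexperiment_result <- function(x, ...) {
  cfg <- x$cfg
  cat("vExperiment:", cfg$mechanism$release_mode, "mechanism,",
      cfg$dose_objects, "Dose objects,", cfg$n_trials, "trials x",
      cfg$duration_cycles, "cycles,", cfg$n_lobules, "lobules\n")
  tmax <- nrow(x$body_mean)
  cat(sprintf("  Body ALT at end: mean %.1f [%.0f, %.0f]\n",
              x$body_mean[tmax, "ALT"], x$body_min[tmax, "ALT"],
              x$body_max[tmax, "ALT"]))
  cat(sprintf("  PC Necrosis-Trigger median: %.1f min;  PC ever-leak-triggered: %.1f%%\n",
              necrosis_trigger_median_min(x),
              100 * mean(x$leak_frac)))
  invisible(x)
}
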