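# YAML configuration loading/saving and run manifests.

#' Load a vExperiment configuration from YAML
#'
#' The file has sections `lobule`, `flow`, `gradients`, `mechanism`,
#' `bands` and `experiment`; omitted fields take the shipped defaults.
#' Hour-denominated keys (suffix `_h`) are converted to cycles at
#' 1 cycle = 1 s.  All cross-field invariants are validated through the
#' configuration constructors, and each violation reports the offending
#' field.
#'
#' @param path YAML file path.
#' @return a [vexperiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  h2c <- function(x) as.integer(round(x * 3600))
  lob <- if (is.null(y$lobule)) default_lobule_config() else {
    ly <- y$lobule$layers
    if (is.null(ly) || length(ly) != 3L)
      stop("lobule.layers: three layers are required")
    do.call(lobule_config, c(
      list(layers = lapply(ly, function(l)
        list(n_nodes = as.integer(l$n_nodes),
             circumference = as.integer(l$circumference),
             core_length = as.integer(l$core_length)))),
      y$lobule[setdiff(names(y$lobule), "layers")]))
  }
  flw <- do.call(flow_params, if (is.null(y$flow)) list() else y$flow)
  grd <- do.call(gradient_set, if (is.null(y$gradients)) list() else
    lapply(y$gradients, function(gv) {
      if (is.list(gv) && all(c("z", "v") %in% names(gv)))
        list(z = as.numeric(unlist(gv$z)), v = as.numeric(unlist(gv$v)))
      else unlist(gv)
    }))
  mechargs <- if (is.null(y$mechanism)) list() else y$mechanism
  for (f in c("leak_lag", "death_delay")) {
    hk <- paste0(f, "_h"); ck <- paste0(f, "_cycles")
    if (!is.null(mechargs[[hk]])) {
      mechargs[[ck]] <- h2c(unlist(mechargs[[hk]]))
      mechargs[[hk]] <- NULL
    }
  }
  if (!is.null(mechargs$exlt_shift_h)) {
    mechargs$exlt_shift_cycles <- h2c(mechargs$exlt_shift_h)
    mechargs$exlt_shift_h <- NULL
  }
  mechargs <- lapply(mechargs, function(v) if (is.list(v)) unlist(v) else v)
  mch <- do.call(mechanism_config, mechargs)
  bnd <- if (is.null(y$bands)) default_band_config() else
    do.call(band_config, lapply(y$bands, function(v) {
      v <- unlist(v)
      if (length(v) == 2L && v[1] < v[2]) seq.int(v[1], v[2]) else as.integer(v)
    }))
  ex <- if (is.null(y$experiment)) list() else y$experiment
  if (!is.null(ex$dose_mgkg)) {
    ex$dose_objects <- dose_objects_from_mgkg(ex$dose_mgkg)
    ex$dose_mgkg <- NULL
  }
  if (!is.null(ex$duration_h)) {
    ex$duration_cycles <- h2c(ex$duration_h)
    ex$duration_h <- NULL
  }
  do.call(vexperiment_config,
          c(list(lobule = lob, flow = flw, gradients = grd, mechanism = mch,
                 bands = bnd), ex))
}

#' Write a vExperiment configuration to YAML
#'
#' @param cfg a [vexperiment_config()].
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "vexperiment_config"))
  y <- list(
    lobule = list(layers = cfg$lobule$layers,
                  hepatocyte_occupancy = cfg$lobule$hepatocyte_occupancy,
                  ec_occupancy = cfg$lobule$ec_occupancy,
                  fanout = cfg$lobule$fanout,
                  n_lobules_per_liver = cfg$lobule$n_lobules_per_liver),
    flow = unclass(cfg$flow),
    gradients = unclass(cfg$gradients),
    mechanism = unclass(cfg$mechanism)[setdiff(names(cfg$mechanism),
                                               "release_mode_id")],
    bands = unclass(cfg$bands),
    experiment = list(dose_objects = cfg$dose_objects,
                      marker_fraction = cfg$marker_fraction,
                      duration_cycles = cfg$duration_cycles,
                      n_trials = cfg$n_trials, n_lobules = cfg$n_lobules,
                      master_seed = cfg$master_seed))
  yaml::write_yaml(y, path)
  invisible(path)
}

# FNV-1a over the serialized object: a dependency-free content hash for
# run manifests.
fnv1a_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by 16777619 in double space (prime fits in 2^53 budget
    # only piecewise, so split h into 16-bit halves)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Build a run manifest for reproducibility
#'
#' Records the configuration content hash, resolved parameter values, the
#' per-trial seeds, the package version, and the output file inventory.
#' Re-running the manifest's configuration with its seeds reproduces the
#' outputs bit-identically.
#'
#' @param cfg a [vexperiment_config()].
#' @param outputs character vector of produced file paths.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(cfg, outputs = character(0)) {
  stopifnot(inherits(cfg, "vexperiment_config"))
  structure(list(
    config_hash = fnv1a_hash(unclass(cfg)),
    trial_seeds = cfg$master_seed + seq_len(cfg$n_trials),
    package_version = as.character(utils::packageVersion("hepaltsim")),
    dose_objects = cfg$dose_objects,
    release_mode = cfg$mechanism$release_mode,
    duration_cycles = cfg$duration_cycles,
    n_lobules = cfg$n_lobules,
    outputs = outputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
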