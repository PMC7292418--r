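# Configuration constructors and validators for flow, gradients, the
# release mechanism, and whole vExperiments.

#' Flow parameters for compound percolation
#'
#' All values are per-object, per-cycle probabilities (one cycle maps to
#' one second).
#'
#' @param dose_transfer_fraction fraction of Body APAP (and Marker) moved
#'   to the Portal Vein each cycle.
#' @param downstream_prob probability a mobile extracellular compound
#'   advances one Sinusoid Segment toward the Central Vein.
#' @param entry_prob probability an extracellular membrane-crossing
#'   compound enters a cell of the local segment.
#' @param exit_prob probability an intracellular free compound exits to the
#'   extracellular space.
#' @param ec_bind_prob,ec_release_prob vEC non-specific APAP binder
#'   kinetics.
#' @param hpc_bind_prob,hpc_release_prob intracellular vHPC APAP binder
#'   kinetics.
#' @return an object of class `flow_params`.
#' @export
flow_params <- function(dose_transfer_fraction = 0.005,
                        downstream_prob = 0.6,
                        entry_prob = 0.18,
                        exit_prob = 0.10,
                        ec_bind_prob = 0.03,
                        ec_release_prob = 0.05,
                        hpc_bind_prob = 0.03,
                        hpc_release_prob = 0.05) {
  p <- structure(as.list(environment()), class = "flow_params")
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("flow parameter ", f, " must be a probability in [0, 1]")
  }
  p
}

#' Periportal-to-pericentral gradient set
#'
#' Each gradient is piecewise linear in the normalized zonal coordinate
#' `z` (0 at PV, 1 at CV).  A gradient may be given as a plain
#' two-element vector `c(value at z = 0, value at z = 1)` (one linear
#' segment) or as `list(z = knots, v = values)` for multi-segment curves
#' (the shipped defaults concentrate metabolism and NAPQI formation
#' pericentrally, mirroring CYP2E1 zonation).  Monotonicity is validated
#' at construction: metabolism and NAPQI-fraction probabilities increase
#' PP-to-PC, the GSH depletion threshold and the MitoD mitigation
#' probability decrease PP-to-PC, and the nonMD mitigation probability
#' increases PP-to-PC.
#'
#' @param p_metabolism per-cycle probability an intracellular free APAP is
#'   metabolized; increasing in `z`.
#' @param p_napqi probability a metabolism event yields NAPQI (the
#'   remainder splits equally between G and S); increasing in `z`.
#' @param gsh_threshold initial GSH-depletion counter value; decreasing in
#'   `z`; a counter value of 0 maps to effective GSH depletion.
#' @param p_mitigate_mitod per-cycle probability of one MitoD removal
#'   event; decreasing in `z`.
#' @param p_mitigate_nonmd per-cycle probability of one nonMD removal
#'   event; increasing in `z`.
#' @param p_mito_fraction probability a damage burst is MitoD (vs nonMD).
#' @return an object of class `gradient_set`.
#' @export
gradient_set <- function(p_metabolism = list(z = c(0, 0.7, 1),
                                             v = c(0.001, 0.02, 0.5)),
                         p_napqi = list(z = c(0, 0.7, 1),
                                        v = c(0.005, 0.25, 0.98)),
                         gsh_threshold = list(z = c(0, 0.7, 1),
                                              v = c(14, 3, 1)),
                         p_mitigate_mitod = list(z = c(0, 0.7, 1),
                                                 v = c(0.2, 0.006, 0.0005)),
                         p_mitigate_nonmd = list(z = c(0, 0.7, 1),
                                                 v = c(0.0005, 0.05, 0.2)),
                         p_mito_fraction = 0.65) {
  norm <- function(gv, what) {
    if (is.numeric(gv) && length(gv) == 2L)
      gv <- list(z = c(0, 1), v = as.numeric(gv))
    if (!is.list(gv) || !all(c("z", "v") %in% names(gv)) ||
        length(gv$z) != length(gv$v) || length(gv$z) < 2L)
      stop(what, ": a gradient is c(v0, v1) or list(z = knots, v = values)")
    if (gv$z[1] != 0 || gv$z[length(gv$z)] != 1 || is.unsorted(gv$z, strictly = TRUE))
      stop(what, ": knots must increase strictly from 0 to 1")
    gv
  }
  g <- structure(list(p_metabolism = norm(p_metabolism, "p_metabolism"),
                      p_napqi = norm(p_napqi, "p_napqi"),
                      gsh_threshold = norm(gsh_threshold, "gsh_threshold"),
                      p_mitigate_mitod = norm(p_mitigate_mitod, "p_mitigate_mitod"),
                      p_mitigate_nonmd = norm(p_mitigate_nonmd, "p_mitigate_nonmd"),
                      p_mito_fraction = p_mito_fraction),
                 class = "gradient_set")
  probs <- c("p_metabolism", "p_napqi", "p_mitigate_mitod", "p_mitigate_nonmd")
  for (f in probs) {
    v <- g[[f]]$v
    if (any(v < 0) || any(v > 1))
      stop(f, " values must be probabilities in [0, 1]")
  }
  if (any(g$gsh_threshold$v < 0))
    stop("gsh_threshold values must be non-negative")
  incr <- function(v) !is.unsorted(v, strictly = TRUE)
  decr <- function(v) !is.unsorted(rev(v), strictly = TRUE)
  if (!incr(g$p_metabolism$v)) stop("p_metabolism must increase PP-to-PC")
  if (!incr(g$p_napqi$v)) stop("p_napqi must increase PP-to-PC")
  if (!decr(g$gsh_threshold$v)) stop("gsh_threshold must decrease PP-to-PC")
  if (!decr(g$p_mitigate_mitod$v))
    stop("p_mitigate_mitod must decrease PP-to-PC")
  if (!incr(g$p_mitigate_nonmd$v))
    stop("p_mitigate_nonmd must increase PP-to-PC")
  if (g$p_mito_fraction < 0 || g$p_mito_fraction > 1)
    stop("p_mito_fraction must be in [0, 1]")
  g
}

release_modes <- c("NECROTIC_ONLY", "MITOD", "NONMD", "DUAL")

#' ALT release mechanism configuration
#'
#' Houses the release-mode variant, damage thresholds, lag-time
#' distributions, and the amplification range of damage-product bursts.
#' Lag times are uniform integer draws from `[min, max)` cycles; the
#' extended-lag-time (exLT) variant shifts both distributions by
#' `exlt_shift_cycles`.
#'
#' @param release_mode one of `"NECROTIC_ONLY"`, `"MITOD"`, `"NONMD"`,
#'   `"DUAL"`.
#' @param dual_semantics `"sum"` (compare MitoD + nonMD to the threshold)
#'   or `"both"` (each must exceed it separately).
#' @param leakage_threshold damage amount that must be exceeded (strict)
#'   to trigger leakage.
#' @param necrosis_threshold MitoD amount that must be exceeded (strict)
#'   to trigger necrosis.
#' @param napqi_removal_prob per-NAPQI, per-cycle removal probability.
#' @param amplification_range integer range `c(min, max)` for the draw
#'   `n`; each post-depletion NAPQI removal creates `n + 1` damage
#'   products of one type.
#' @param leak_lag_cycles,death_delay_cycles `[min, max)` in cycles.
#' @param exlt_shift_cycles shift added to both lag distributions
#'   (1600 for the exLT variant).
#' @param alt_initial ALT objects per vHPC at t = 0.
#' @param seconds_per_cycle fixed at 1; hour-denominated inputs are
#'   converted with this factor.
#' @return an object of class `mechanism_config`.
#' @export
mechanism_config <- function(release_mode = "MITOD",
                             dual_semantics = "sum",
                             leakage_threshold = 1L,
                             necrosis_threshold = 4L,
                             napqi_removal_prob = 0.5,
                             amplification_range = c(3L, 6L),
                             leak_lag_cycles = c(2700L, 18000L),
                             death_delay_cycles = c(7200L, 21600L),
                             exlt_shift_cycles = 0L,
                             alt_initial = 5L,
                             seconds_per_cycle = 1L) {
  release_mode <- match.arg(release_mode, release_modes)
  dual_semantics <- match.arg(dual_semantics, c("sum", "both"))
  m <- structure(
    list(release_mode = release_mode,
         release_mode_id = match(release_mode, release_modes) - 1L,
         dual_semantics = dual_semantics,
         leakage_threshold = as.integer(leakage_threshold),
         necrosis_threshold = as.integer(necrosis_threshold),
         napqi_removal_prob = napqi_removal_prob,
         amplification_range = as.integer(amplification_range),
         leak_lag_cycles = as.integer(leak_lag_cycles),
         death_delay_cycles = as.integer(death_delay_cycles),
         exlt_shift_cycles = as.integer(exlt_shift_cycles),
         alt_initial = as.integer(alt_initial),
         seconds_per_cycle = as.integer(seconds_per_cycle)),
    class = "mechanism_config")
  if (m$leakage_threshold < 0 || m$necrosis_threshold < 0)
    stop("thresholds must be >= 0")
  if (m$napqi_removal_prob < 0 || m$napqi_removal_prob > 1)
    stop("napqi_removal_prob must be in [0, 1]")
  if (m$amplification_range[1] > m$amplification_range[2] ||
      m$amplification_range[1] < 0)
    stop("invalid amplification_range")
  for (f in c("leak_lag_cycles", "death_delay_cycles"))
    if (m[[f]][1] >= m[[f]][2]) stop(f, ": min must be < max")
  if (m$leak_lag_cycles[1] >= m$death_delay_cycles[1])
    stop("the minimum ALT Leakage lag time must be less than the minimum ",
         "Necrosis death delay")
  if (m$alt_initial < 0) stop("alt_initial must be >= 0")
  m
}

#' Convert a wet-lab dose in mg/kg to Dose objects
#'
#' Linear mapping `objects = round(mg/kg * 500 / 3)`, so 150, 300 and
#' 600 mg/kg map to the low (25,000), medium (50,000) and high (100,000)
#' object Doses; doses above 100,000 objects are rejected.
#'
#' @param mgkg dose in mg per kg body weight.
#' @return integer number of APAP Dose objects.
#' @export
dose_objects_from_mgkg <- function(mgkg) {
  obj <- as.integer(round(mgkg * 500 / 3))
  if (obj > 100000L) stop("APAP Doses are <= 100,000 objects (600 mg/kg)")
  if (obj < 0L) stop("dose must be non-negative")
  obj
}

#' Assemble a vExperiment configuration
#'
#' @param lobule lobule structural configuration ([lobule_config()]).
#' @param flow [flow_params()].
#' @param gradients [gradient_set()].
#' @param mechanism [mechanism_config()].
#' @param bands [band_config()].
#' @param dose_objects APAP Dose size in objects (<= 100,000).
#' @param marker_fraction Marker objects dosed alongside APAP, as a
#'   fraction of the APAP Dose.
#' @param duration_cycles trial length (default 21,600 = 6 h).
#' @param n_trials Monte Carlo trials per vExperiment (default 12; use
#'   more for small doses).
#' @param n_lobules lobules per vLiver for this experiment; defaults to
#'   the lobule config's `n_lobules_per_liver`.
#' @param master_seed integer; trial i runs with seed `master_seed + i`.
#' @return an object of class `vexperiment_config`.
#' @export
vexperiment_config <- function(lobule = default_lobule_config(),
                               flow = flow_params(),
                               gradients = gradient_set(),
                               mechanism = mechanism_config(),
                               bands = default_band_config(),
                               dose_objects = 50000L,
                               marker_fraction = 0.1,
                               duration_cycles = 21600L,
                               n_trials = 12L,
                               n_lobules = NULL,
                               master_seed = 1L) {
  stopifnot(inherits(lobule, "lobule_config"), inherits(flow, "flow_params"),
            inherits(gradients, "gradient_set"),
            inherits(mechanism, "mechanism_config"),
            inherits(bands, "band_config"))
  if (dose_objects > 100000L) stop("APAP Doses are <= 100,000 objects")
  if (dose_objects < 0L) stop("dose must be non-negative")
  if (duration_cycles < 1L) stop("duration_cycles must be >= 1")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  structure(list(lobule = lobule, flow = flow, gradients = gradients,
                 mechanism = mechanism, bands = bands,
                 dose_objects = as.integer(dose_objects),
                 marker_fraction = marker_fraction,
                 duration_cycles = as.integer(duration_cycles),
                 n_trials = as.integer(n_trials),
                 n_lobules = if (is.null(n_lobules)) lobule$n_lobules_per_liver
                             else as.integer(n_lobules),
                 master_seed = as.integer(master_seed)),
            class = "vexperiment_config")
}
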