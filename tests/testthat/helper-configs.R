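# Shared miniature configurations for fast engine tests.

# small but non-degenerate lobule (a few hundred vHPCs)
small_lobule <- function() {
  lobule_config(layers = list(
    list(n_nodes = c(3L, 4L), circumference = c(4L, 6L), core_length = c(2L, 4L)),
    list(n_nodes = c(3L, 3L), circumference = c(4L, 5L), core_length = c(2L, 3L)),
    list(n_nodes = c(2L, 3L), circumference = c(4L, 5L), core_length = c(2L, 3L))))
}

# one vHPC per node, 3-node chain; fully deterministic when all probs are 0/1
unit_chain_lobule <- function() {
  lobule_config(layers = list(
    list(n_nodes = c(1L, 1L), circumference = c(1L, 1L), core_length = c(1L, 1L)),
    list(n_nodes = c(1L, 1L), circumference = c(1L, 1L), core_length = c(1L, 1L)),
    list(n_nodes = c(1L, 1L), circumference = c(1L, 1L), core_length = c(1L, 1L))),
    fanout = c(1L, 1L), n_lobules_per_liver = 1L)
}

# band cuts suited to the short paths of the small lobule (the default
# cuts assume full-size path lengths and would overlap here)
small_bands <- function() band_config(pp_dpv = 1L, mz_dcv = 2L, pc_dcv = 1L)

small_cfg <- function(release_mode = "MITOD", dose = 2000L,
                      duration = 1200L, n_trials = 2L, seed = 1L, ...) {
  vexperiment_config(
    lobule = small_lobule(),
    mechanism = mechanism_config(release_mode = release_mode),
    bands = small_bands(),
    dose_objects = dose, duration_cycles = duration,
    n_trials = n_trials, n_lobules = 1L, master_seed = seed, ...)
}

# gradients with mitigation effectively disabled (validator requires strict
# monotonicity, so use a negligible epsilon)
no_mitigation_gradients <- function() {
  g <- gradient_set()
  g$p_mitigate_mitod <- list(z = c(0, 1), v = c(0, 0))
  g$p_mitigate_nonmd <- list(z = c(0, 1), v = c(0, 0))
  g
}
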