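# Shipped default configurations.
#
# The structural sampling ranges are free parameters of the framework (the
# source anatomy references do not pin them); the values below were fixed
# once by calibrating against the reference structural statistics: a mean
# of ~16,165 vHPCs per lobule, ~85.3% of vHPCs at dPV 1-14, ~14.1% at dCV
# 1-12 (of the remainder), right-skewed dPV distances, and band means near
# 4772 (PP), 1721 (MZ) and 906 (PC).  See calibrate_structure() for the
# search procedure.

#' Default lobule structural configuration
#'
#' Calibrated so that Monte-Carlo sampled lobules reproduce the reference
#' structural statistics (see package vignette).
#' @return a [lobule_config()].
#' @export
default_lobule_config <- function() {
  lobule_config(layers = list(
    list(n_nodes = c(37L, 48L), circumference = c(29L, 32L),
         core_length = c(5L, 13L)),
    list(n_nodes = c(29L, 34L), circumference = c(30L, 32L),
         core_length = c(2L, 7L)),
    list(n_nodes = c(16L, 21L), circumference = c(17L, 20L),
         core_length = c(4L, 8L))))
}

#' Default lobular band configuration
#'
#' Band cut points chosen on the default structure so that mean band
#' counts match the reference values: PP = dPV 1-4, MZ = dCV 4-7 (the
#' mid-lobule positions immediately upstream of PC), PC = dCV 1-3.
#' Bands are partial covers; the remaining positions are unbanded.
#' @return a [band_config()].
#' @export
default_band_config <- function() {
  band_config(pp_dpv = 1:4, mz_dcv = 4:7, pc_dcv = 1:3)
}

#' Default medium-dose MitoD-Caused vExperiment configuration
#'
#' The shipped kinetic defaults (flow and gradient endpoints) were fixed
#' by calibration against the reference pericentral timing statistics
#' (median PC Necrosis-Trigger time and the PC Leakage-Triggered fraction
#' at 30 min) at the medium Dose; see the methods vignette.
#'
#' @param release_mode release mechanism variant (default `"MITOD"`).
#' @param dose_objects APAP Dose (default medium, 50,000 objects =
#'   300 mg/kg).
#' @param n_lobules lobules per vLiver (default 4, the reduced liver used
#'   for kinetic work; structural summaries use the full 12).
#' @param ... passed to [vexperiment_config()].
#' @return a [vexperiment_config()].
#' @export
default_vexperiment_config <- function(release_mode = "MITOD",
                                       dose_objects = 50000L,
                                       n_lobules = 4L, ...) {
  vexperiment_config(
    lobule = default_lobule_config(),
    flow = flow_params(),
    gradients = gradient_set(),
    mechanism = mechanism_config(release_mode = release_mode),
    bands = default_band_config(),
    dose_objects = dose_objects,
    n_lobules = n_lobules, ...)
}
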