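# Reference (pure-R) per-vHPC event logic: zonated metabolism, GSH
# depletion, damage creation/amplification, mitigation, necrosis with
# death delay, and the four ALT-externalization mechanisms.  These mirror
# the compiled engine's semantics one vHPC at a time and back the
# enumeration-oracle tests.

#' Evaluate a piecewise-linear gradient at zonal coordinate z
#'
#' @param g either `c(value at z = 0, value at z = 1)` or
#'   `list(z = knots, v = values)` as stored in a [gradient_set()].
#' @param z zonal coordinate(s) in \[0, 1\].
#' @return interpolated value(s).
#' @export
grad_value <- function(g, z) {
  if (is.numeric(g) && length(g) == 2L)
    return(g[1] + (g[2] - g[1]) * z)
  stats::approx(g$z, g$v, xout = z, rule = 2)$y
}

#' Construct a single vHPC state
#'
#' @param zone zonal coordinate z in \[0, 1\] (0 = PV, 1 = CV).
#' @param gradients a [gradient_set()]; sets the location-determined
#'   initial GSH counter.
#' @param alt_initial ALT objects held at t = 0.
#' @return an object of class `hepatocyte_state`.
#' @export
hepatocyte_state <- function(zone, gradients = gradient_set(),
                             alt_initial = 5L) {
  structure(list(
    zone = zone,
    apap_free = 0L, apap_bound = 0L, g = 0L, s = 0L, napqi = 0L,
    mitoD = 0L, nonMD = 0L, pap = 0L,
    gsh_counter = grad_value(gradients$gsh_threshold, zone),
    alt_counter = as.integer(alt_initial),
    pending = integer(0),
    leakage_triggered = FALSE, ever_leak_triggered = FALSE,
    necrosis_triggered = FALSE, necrotic_due_cycle = NA_integer_,
    necrotic = FALSE,
    released = 0L, last_externalized = 0L), class = "hepatocyte_state")
}

unif_int <- function(lo, hi_excl) {
  if (hi_excl - lo <= 1L) return(as.integer(lo))
  lo + sample.int(hi_excl - lo, 1L) - 1L
}

#' Zonated APAP metabolism
#'
#' Each free intracellular APAP is metabolized with probability
#' `p_metabolism(z)`; the metabolite is NAPQI with probability
#' `p_napqi(z)`, otherwise it is G or S with equal probability.  Every
#' metabolized APAP is conserved into exactly one product.
#'
#' @param h a [hepatocyte_state()].
#' @param gradients a [gradient_set()].
#' @return the updated state.
#' @export
metabolize_step <- function(h, gradients) {
  if (h$necrotic) return(h)
  m <- stats::rbinom(1L, h$apap_free, grad_value(gradients$p_metabolism, h$zone))
  if (m > 0L) {
    h$apap_free <- h$apap_free - m
    nn <- stats::rbinom(1L, m, grad_value(gradients$p_napqi, h$zone))
    gg <- stats::rbinom(1L, m - nn, 0.5)
    h$napqi <- h$napqi + nn
    h$g <- h$g + gg
    h$s <- h$s + (m - nn - gg)
  }
  h
}

#' NAPQI removal: GSH depletion, then amplified damage-product bursts
#'
#' Each NAPQI is removed with `napqi_removal_prob` per cycle.  While the
#' GSH counter is positive a removal decrements it by 1.0 and creates no
#' damage; once the counter is 0 (effective GSH depletion) each removal
#' creates `n + 1` damage products of a single type (MitoD with
#' probability `p_mito_fraction`, else nonMD), `n` drawn uniformly from
#' the integer amplification range.
#'
#' @param h a [hepatocyte_state()].
#' @param mech a [mechanism_config()].
#' @param gradients a [gradient_set()] (supplies `p_mito_fraction`).
#' @return the updated state.
#' @export
napqi_removal_step <- function(h, mech, gradients = gradient_set()) {
  if (h$necrotic) return(h)
  nr <- stats::rbinom(1L, h$napqi, mech$napqi_removal_prob)
  for (i in seq_len(nr)) {
    h$napqi <- h$napqi - 1L
    if (h$gsh_counter > 0) {
      h$gsh_counter <- max(0, h$gsh_counter - 1)
    } else {
      amp <- unif_int(mech$amplification_range[1],
                      mech$amplification_range[2] + 1L)
      prod <- amp + 1L
      if (stats::runif(1L) < gradients$p_mito_fraction)
        h$mitoD <- h$mitoD + prod
      else h$nonMD <- h$nonMD + prod
    }
  }
  h
}

#' Damage mitigation: at most one removal per damage type per cycle
#'
#' @param h a [hepatocyte_state()].
#' @param gradients a [gradient_set()].
#' @return the updated state.
#' @export
mitigation_step <- function(h, gradients) {
  if (h$necrotic) return(h)
  if (h$mitoD > 0L &&
      stats::runif(1L) < grad_value(gradients$p_mitigate_mitod, h$zone))
    h$mitoD <- h$mitoD - 1L
  if (h$nonMD > 0L &&
      stats::runif(1L) < grad_value(gradients$p_mitigate_nonmd, h$zone))
    h$nonMD <- h$nonMD - 1L
  h
}

#' Necrosis trigger, death delay, and necrotic ALT release
#'
#' When MitoD strictly exceeds the Necrosis Threshold the vHPC becomes
#' Necrosis-Triggered and draws a Death Delay from the uniform
#' `[min, max)` distribution (plus the exLT shift).  At the due cycle the
#' vHPC becomes Necrotic: all remaining counted ALT is externalized with
#' zero delay, and the vHPC performs no further events.
#'
#' @param h a [hepatocyte_state()].
#' @param mech a [mechanism_config()].
#' @param t current cycle.
#' @return the updated state; `h$last_externalized` holds the number of
#'   ALT objects externalized this call.
#' @export
necrosis_step <- function(h, mech, t) {
  h$last_externalized <- 0L
  if (h$necrotic) return(h)
  if (h$necrosis_triggered && !is.na(h$necrotic_due_cycle) &&
      t >= h$necrotic_due_cycle) {
    h$necrotic <- TRUE
    h$last_externalized <- h$alt_counter
    h$released <- h$released + h$alt_counter
    h$alt_counter <- 0L
    return(h)
  }
  if (!h$necrosis_triggered && h$mitoD > mech$necrosis_threshold) {
    h$necrosis_triggered <- TRUE
    dd <- mech$death_delay_cycles + mech$exlt_shift_cycles
    h$necrotic_due_cycle <- t + unif_int(dd[1], dd[2])
  }
  h
}

#' Damage-triggered ALT leakage
#'
#' The trigger test depends on the release mode: MitoD-Caused compares
#' MitoD, nonMD-Caused compares nonMD, and Dual-Cause compares either the
#' sum (default) or both amounts separately to the ALT Leakage Threshold
#' (strict).  While triggered, one release is scheduled per cycle (bounded
#' by unscheduled ALT) at a lag drawn uniformly from `[min, max)` (plus
#' the exLT shift).  Scheduled releases fire at their due cycle iff the
#' ALT counter is positive, each creating one externalized ALT object.  If
#' damage falls back below threshold the vHPC is no longer
#' Leakage-Triggered, but already-scheduled releases persist.  No-op for
#' the Necrotic-only mode.
#'
#' @param h a [hepatocyte_state()].
#' @param mech a [mechanism_config()].
#' @param t current cycle.
#' @return the updated state; `h$last_externalized` holds the ALT
#'   externalized this call.
#' @export
leakage_step <- function(h, mech, t) {
  h$last_externalized <- 0L
  if (mech$release_mode == "NECROTIC_ONLY" || h$necrotic) return(h)
  # fire due releases
  due <- h$pending <= t
  n_due <- sum(due)
  if (n_due > 0L) {
    n_rel <- min(n_due, h$alt_counter)
    h$alt_counter <- h$alt_counter - n_rel
    h$released <- h$released + n_rel
    h$last_externalized <- n_rel
    h$pending <- h$pending[!due]
  }
  trig <- switch(mech$release_mode,
    MITOD = h$mitoD > mech$leakage_threshold,
    NONMD = h$nonMD > mech$leakage_threshold,
    DUAL = if (mech$dual_semantics == "sum")
      h$mitoD + h$nonMD > mech$leakage_threshold
    else h$mitoD > mech$leakage_threshold && h$nonMD > mech$leakage_threshold)
  if (trig && !h$ever_leak_triggered) h$ever_leak_triggered <- TRUE
  h$leakage_triggered <- trig
  if (trig && h$alt_counter - length(h$pending) > 0L) {
    ll <- mech$leak_lag_cycles + mech$exlt_shift_cycles
    h$pending <- c(h$pending, t + unif_int(ll[1], ll[2]))
  }
  h
}

#' Optional APAP <-> p-aminophenol futile cycle
#'
#' Reversible interconversion with per-cycle probabilities; total
#' APAP + pAP is conserved.  Disabled by default.
#'
#' @param h a [hepatocyte_state()].
#' @param forward_prob,reverse_prob per-object, per-cycle probabilities.
#' @param enabled feature flag (default FALSE: state unchanged).
#' @return the updated state.
#' @export
futile_cycle_step <- function(h, forward_prob = 0, reverse_prob = 0,
                              enabled = FALSE) {
  if (!enabled || h$necrotic) return(h)
  fwd <- stats::rbinom(1L, h$apap_free, forward_prob)
  rev <- stats::rbinom(1L, h$pap, reverse_prob)
  h$apap_free <- h$apap_free - fwd + rev
  h$pap <- h$pap + fwd - rev
  h
}
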