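# Reference (pure-R) compound-transport steps at Sinusoid-Segment
# granularity.  These implement the same movement semantics as the
# compiled trial engine and are the unit-testable surface for the
# transport operations; whole trials run through the engine.

#' Compound kind properties
#'
#' @return data.frame of the mobile compound kinds with their membrane
#'   properties.  NAPQI and the damage products are intracellular
#'   bookkeeping only and never appear in extracellular pools.
#' @export
compound_kinds <- function() {
  data.frame(
    name = c("APAP", "G", "S", "ALT", "Marker"),
    membrane_crossing = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    extracellular_only = c(FALSE, FALSE, FALSE, TRUE, TRUE))
}

#' Initialize a transport state for a lobule graph
#'
#' Mobile compound pools per Sinusoid Segment (plus a Central Vein
#' staging row), vEC binder occupancy, node-aggregated intracellular
#' pools, and Mouse-Body amounts.  The APAP Dose (and Marker) starts in
#' Body.
#'
#' @param graph a `lobule_graph`.
#' @param dose_objects APAP Dose (<= 100,000 objects).
#' @param marker_objects Marker internal-standard objects.
#' @return an object of class `transport_state`.
#' @export
transport_state <- function(graph, dose_objects, marker_objects = 0L) {
  stopifnot(inherits(graph, "lobule_graph"))
  if (dose_objects > 100000L) stop("APAP Doses are <= 100,000 objects")
  if (dose_objects < 0L) stop("dose must be non-negative")
  n <- nrow(graph$nodes)
  kinds <- compound_kinds()$name
  ex <- matrix(0L, n + 1L, length(kinds),
               dimnames = list(NULL, kinds))  # row n+1 = CV staging
  cell <- matrix(0L, n, 4L,
                 dimnames = list(NULL, c("apap_free", "apap_bound", "G", "S")))
  structure(list(
    ex = ex, cell = cell,
    ec_bound = integer(n), ec_cap = graph$nodes$n_vec,
    body = c(APAP = as.numeric(dose_objects), G = 0, S = 0, ALT = 0,
             Marker = as.numeric(marker_objects)),
    initial_dose = as.integer(dose_objects),
    initial_marker = as.integer(marker_objects),
    cum_metabolized = 0L), class = "transport_state")
}

#' Transfer a fraction of Body APAP (and Marker) to the Portal Vein
#'
#' Binomially thinned transfer; arriving objects are spread uniformly
#' over the layer-1 Sinusoid Segments.
#'
#' @param state a `transport_state`.
#' @param graph the `lobule_graph`.
#' @param params a [flow_params()].
#' @return the updated state.
#' @export
dose_step <- function(state, graph, params) {
  l1 <- which(graph$nodes$layer == 1L)
  for (kind in c("APAP", "Marker")) {
    k <- stats::rbinom(1L, as.integer(state$body[kind]),
                       params$dose_transfer_fraction)
    if (k > 0L) {
      state$body[kind] <- state$body[kind] - k
      tgt <- if (length(l1) == 1L) rep(l1, k) else sample(l1, k, replace = TRUE)
      tb <- table(tgt)
      state$ex[as.integer(names(tb)), kind] <-
        state$ex[as.integer(names(tb)), kind] + as.integer(tb)
    }
  }
  state
}

#' Advance mobile extracellular compounds one step toward the CV
#'
#' Each mobile object independently advances one Sinusoid Segment with
#' probability `downstream_prob` (at most one grid step per cycle);
#' objects leaving a layer-3 segment land on the CV staging row.  Nodes
#' are processed CV-side first so no object moves twice.  Per-kind totals
#' are conserved.
#'
#' @inheritParams dose_step
#' @return the updated state.
#' @export
percolate_step <- function(state, graph, params) {
  n <- nrow(graph$nodes)
  cv_row <- n + 1L
  adj <- split(ifelse(graph$edges$to == cv_row, cv_row, graph$edges$to),
               graph$edges$from)
  for (nd in order(-graph$nodes$layer)) {
    nbr <- adj[[as.character(nd)]]
    if (is.null(nbr)) next
    for (kind in colnames(state$ex)) {
      cnt <- state$ex[nd, kind]
      if (cnt == 0L) next
      mv <- stats::rbinom(1L, cnt, params$downstream_prob)
      if (mv == 0L) next
      state$ex[nd, kind] <- state$ex[nd, kind] - mv
      tgt <- if (length(nbr) == 1L) rep(nbr, mv) else sample(nbr, mv, replace = TRUE)
      tb <- table(tgt)
      state$ex[as.integer(names(tb)), kind] <-
        state$ex[as.integer(names(tb)), kind] + as.integer(tb)
    }
  }
  state
}

#' Cell entry, exit and non-specific binder exchange
#'
#' Only membrane-crossing kinds may enter cells (the Marker never does);
#' APAP additionally exchanges with vEC and intracellular binders, and
#' bound objects are immobile for the cycle.  Metabolite (G, S) re-uptake
#' is neglected: they cross outward only.
#'
#' @inheritParams dose_step
#' @return the updated state.
#' @export
cell_exchange_step <- function(state, graph, params) {
  n <- nrow(graph$nodes)
  for (nd in seq_len(n)) {
    # vEC binders: release then bind, capped by vEC capacity
    rls <- stats::rbinom(1L, state$ec_bound[nd], params$ec_release_prob)
    state$ec_bound[nd] <- state$ec_bound[nd] - rls
    state$ex[nd, "APAP"] <- state$ex[nd, "APAP"] + rls
    bnd <- min(stats::rbinom(1L, state$ex[nd, "APAP"], params$ec_bind_prob),
               state$ec_cap[nd] - state$ec_bound[nd])
    state$ec_bound[nd] <- state$ec_bound[nd] + bnd
    state$ex[nd, "APAP"] <- state$ex[nd, "APAP"] - bnd
    # exits (free intracellular, outward crossing)
    for (kk in c("G", "S")) {
      k <- stats::rbinom(1L, state$cell[nd, kk], params$exit_prob)
      state$cell[nd, kk] <- state$cell[nd, kk] - k
      state$ex[nd, kk] <- state$ex[nd, kk] + k
    }
    k <- stats::rbinom(1L, state$cell[nd, "apap_free"], params$exit_prob)
    state$cell[nd, "apap_free"] <- state$cell[nd, "apap_free"] - k
    state$ex[nd, "APAP"] <- state$ex[nd, "APAP"] + k
    # intracellular binder exchange
    kr <- stats::rbinom(1L, state$cell[nd, "apap_bound"], params$hpc_release_prob)
    state$cell[nd, "apap_bound"] <- state$cell[nd, "apap_bound"] - kr
    state$cell[nd, "apap_free"] <- state$cell[nd, "apap_free"] + kr
    kb <- stats::rbinom(1L, state$cell[nd, "apap_free"], params$hpc_bind_prob)
    state$cell[nd, "apap_free"] <- state$cell[nd, "apap_free"] - kb
    state$cell[nd, "apap_bound"] <- state$cell[nd, "apap_bound"] + kb
    # entry: APAP only (Marker and ALT are extracellular-only)
    ke <- stats::rbinom(1L, state$ex[nd, "APAP"], params$entry_prob)
    state$ex[nd, "APAP"] <- state$ex[nd, "APAP"] - ke
    state$cell[nd, "apap_free"] <- state$cell[nd, "apap_free"] + ke
  }
  state
}

#' Move every compound on the CV staging row to Mouse Body
#'
#' ALT accumulates in Body and is never removed (no plasma clearance) and
#' does not re-enter the vLiver.
#'
#' @inheritParams dose_step
#' @return the updated state.
#' @export
cv_collect_step <- function(state, graph) {
  cv <- nrow(state$ex)
  state$body <- state$body + state$ex[cv, ]
  state$ex[cv, ] <- 0L
  state
}

#' Per-kind object totals for a transport state (ledger view)
#'
#' @param state a `transport_state`.
#' @return named vector of whole-Mouse totals per kind; with no
#'   metabolism applied these are invariant under every transport step.
#' @export
transport_totals <- function(state) {
  c(APAP = unname(state$body["APAP"]) + sum(state$ex[, "APAP"]) +
      sum(state$ec_bound) + sum(state$cell[, c("apap_free", "apap_bound")]),
    G = unname(state$body["G"]) + sum(state$ex[, "G"]) + sum(state$cell[, "G"]),
    S = unname(state$body["S"]) + sum(state$ex[, "S"]) + sum(state$cell[, "S"]),
    ALT = unname(state$body["ALT"]) + sum(state$ex[, "ALT"]),
    Marker = unname(state$body["Marker"]) + sum(state$ex[, "Marker"]))
}
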