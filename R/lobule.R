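# Lobule graph construction and zonal position metrics.
#
# A vLobule is a three-layer directed acyclic graph of Sinusoid Segments
# (SS).  Flow enters every layer-1 node from the Portal Vein (PV, node id
# 0) and leaves every layer-3 node into the Central Vein (CV, node id
# n_nodes + 1).  Each SS is a quasi-3D grid (circumference x core length)
# whose hepatocyte space is partially occupied by vHPC agents.  All SS
# dimensions are Monte-Carlo sampled per lobule.

#' Construct a lobule structural configuration
#'
#' Defines the sampling ranges from which every Monte-Carlo lobule graph is
#' drawn: per-layer node counts, Sinusoid Segment grid dimensions
#' (circumference and core length, in grid points), cell occupancies, and
#' the downstream fan-out rule.  The shipped defaults (see
#' [default_lobule_config()]) are calibrated so that sampled lobules
#' reproduce the reference structural statistics (mean vHPCs per lobule and
#' the periportal-to-pericentral distance histograms).
#'
#' @param layers list of three lists, one per layer, each with integer
#'   ranges `n_nodes`, `circumference`, `core_length` (each `c(min, max)`,
#'   inclusive).
#' @param hepatocyte_occupancy fraction of hepatocyte-space grid points
#'   occupied by vHPCs (default 0.90).
#' @param ec_occupancy fraction of endothelial-space grid points occupied
#'   by vECs (default 0.99).
#' @param fanout integer range `c(min, max)`: number of downstream
#'   (layer k+1) Sinusoid Segments each layer-k segment feeds.
#' @param n_lobules_per_liver number of sampled lobule variants composing a
#'   vLiver (default 12).
#' @return an object of class `lobule_config`.
#' @export
lobule_config <- function(layers,
                          hepatocyte_occupancy = 0.90,
                          ec_occupancy = 0.99,
                          fanout = c(1L, 3L),
                          n_lobules_per_liver = 12L) {
  cfg <- structure(
    list(layers = layers,
         hepatocyte_occupancy = hepatocyte_occupancy,
         ec_occupancy = ec_occupancy,
         fanout = as.integer(fanout),
         n_lobules_per_liver = as.integer(n_lobules_per_liver)),
    class = "lobule_config")
  validate_lobule_config(cfg)
  cfg
}

check_range <- function(r, what, min_allowed = 1L) {
  if (length(r) != 2L || anyNA(r) || r[1] > r[2])
    stop("invalid range for ", what, ": must be c(min, max) with min <= max",
         call. = FALSE)
  if (r[1] < min_allowed)
    stop("invalid range for ", what, ": minimum below ", min_allowed,
         call. = FALSE)
  invisible(TRUE)
}

validate_lobule_config <- function(cfg) {
  if (!inherits(cfg, "lobule_config")) stop("not a lobule_config")
  if (length(cfg$layers) != 3L) stop("exactly three layers are required")
  for (k in 1:3) {
    ly <- cfg$layers[[k]]
    check_range(ly$n_nodes, sprintf("layer %d n_nodes", k))
    check_range(ly$circumference, sprintf("layer %d circumference", k))
    check_range(ly$core_length, sprintf("layer %d core_length", k))
  }
  # biomimetic constraint: layer 2 must be able to dominate layer 3
  if (cfg$layers[[3]]$n_nodes[1] > cfg$layers[[2]]$n_nodes[2])
    stop("layer 3 node-count range cannot exceed layer 2 everywhere ",
         "(more SSs in layer 3 than layer 2 is not biomimetic)")
  for (f in c("hepatocyte_occupancy", "ec_occupancy")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(f, " must be in (0, 1]")
  }
  check_range(cfg$fanout, "fanout")
  if (cfg$n_lobules_per_liver < 1L) stop("n_lobules_per_liver must be >= 1")
  invisible(cfg)
}

sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep.int(as.integer(r[1]), n)
  else sample.int(r[2] - r[1] + 1L, n, replace = TRUE) + as.integer(r[1]) - 1L
}

#' Sample a Monte-Carlo lobule graph
#'
#' Draws per-layer node counts and per-node Sinusoid Segment dimensions
#' from the configured ranges, builds the layered PV-to-CV directed acyclic
#' graph, places vHPC agents on the hepatocyte grid at the configured
#' occupancy, and computes the zonal position metrics (see
#' [compute_zonal_positions()]).  Repeated calls with the same seed return
#' identical graphs.
#'
#' @param config a [lobule_config()].
#' @param seed integer seed for the structure random stream.
#' @return an object of class `lobule_graph`: a list with `nodes`
#'   (data.frame: node, layer, circumference, core_length, n_vhpc, n_vec),
#'   `edges` (data.frame: from, to; 0 = PV, n+1 = CV), `vhpc` (data.frame
#'   with one row per occupied core position: node, pos, count, dPV, dCV,
#'   zone, band) and `meta`.
#' @export
sample_lobule_graph <- function(config, seed) {
  validate_lobule_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")

  n_per_layer <- integer(3)
  for (k in 1:3) n_per_layer[k] <- sample_range(config$layers[[k]]$n_nodes)
  # biomimetic constraint: never more SSs in layer 3 than in layer 2
  n_per_layer[3] <- min(n_per_layer[3], n_per_layer[2])

  layer <- rep.int(1:3, n_per_layer)
  n_nodes <- length(layer)
  circ <- integer(n_nodes); clen <- integer(n_nodes)
  for (k in 1:3) {
    idx <- which(layer == k)
    circ[idx] <- sample_range(config$layers[[k]]$circumference, length(idx))
    clen[idx] <- sample_range(config$layers[[k]]$core_length, length(idx))
  }
  n_vhpc_per_pos <- pmax(1L, as.integer(round(config$hepatocyte_occupancy * circ)))
  nodes <- data.frame(
    node = seq_len(n_nodes), layer = layer,
    circumference = circ, core_length = clen,
    n_vhpc = n_vhpc_per_pos * clen,
    n_vec = as.integer(round(config$ec_occupancy * circ)) * clen)

  # edges: PV -> all layer-1; layered fan-out k -> k+1; layer-3 -> CV
  ef <- integer(0); et <- integer(0)
  l1 <- which(layer == 1L)
  ef <- c(ef, rep.int(0L, length(l1))); et <- c(et, l1)
  for (k in 1:2) {
    up <- which(layer == k); dn <- which(layer == k + 1L)
    covered <- logical(length(dn))
    for (u in up) {
      f <- min(sample_range(config$fanout), length(dn))
      tgt <- if (length(dn) == 1L) dn else sample(dn, f)
      ef <- c(ef, rep.int(u, length(tgt))); et <- c(et, tgt)
      covered[match(tgt, dn)] <- TRUE
    }
    for (d in dn[!covered]) {
      u <- if (length(up) == 1L) up else sample(up, 1L)
      ef <- c(ef, u); et <- c(et, d)
    }
  }
  l3 <- which(layer == 3L)
  ef <- c(ef, l3); et <- c(et, rep.int(n_nodes + 1L, length(l3)))
  edges <- data.frame(from = ef, to = et)

  # one row per occupied core position
  vhpc <- data.frame(
    node = rep.int(nodes$node, nodes$core_length),
    pos = sequence(nodes$core_length),
    count = rep.int(n_vhpc_per_pos, nodes$core_length))

  g <- structure(
    list(nodes = nodes, edges = edges, vhpc = vhpc,
         meta = list(seed = as.integer(seed), config = config,
                     layer_mean_length = vapply(1:3, function(k)
                       mean(clen[layer == k]), numeric(1)))),
    class = "lobule_graph")
  compute_zonal_positions(g)
}

#' Compute zonal position metrics (dPV, dCV, zone)
#'
#' A vHPC's distance from the Portal Vein, `dPV`, is 1-based and expressed
#' in Core grid points: the rounded sum of the mean core lengths of all
#' upstream layers plus the position within its own segment.  `dCV` is the
#' symmetric distance from the Central Vein.  The normalized zonal
#' coordinate is `zone = dPV / (dPV + dCV)`, 0 at PV and 1 at CV; it is the
#' argument of every periportal-to-pericentral gradient.
#'
#' @param graph a `lobule_graph`.
#' @return the graph with `dPV`, `dCV` and `zone` columns populated.
#' @export
compute_zonal_positions <- function(graph) {
  stopifnot(inherits(graph, "lobule_graph"))
  check_lobule_connectivity(graph)
  lm <- graph$meta$layer_mean_length
  up_off <- c(0, round(lm[1]), round(lm[1] + lm[2]))
  dn_off <- c(round(lm[2] + lm[3]), round(lm[3]), 0)
  v <- graph$vhpc
  ly <- graph$nodes$layer[v$node]
  len <- graph$nodes$core_length[v$node]
  v$dPV <- as.integer(up_off[ly] + v$pos)
  v$dCV <- as.integer(dn_off[ly] + (len - v$pos + 1L))
  stopifnot(all(v$dPV >= 1L), all(v$dCV >= 1L))
  v$zone <- v$dPV / (v$dPV + v$dCV)
  graph$vhpc <- v
  graph
}

check_lobule_connectivity <- function(graph) {
  n <- nrow(graph$nodes)
  has_in <- unique(graph$edges$to)
  has_out <- unique(graph$edges$from)
  bad <- setdiff(seq_len(n), intersect(has_in, has_out))
  if (length(bad))
    stop("structural error: node(s) ", paste(bad, collapse = ", "),
         " not connected on a PV-to-CV path")
  invisible(TRUE)
}

#' Construct a lobular band configuration
#'
#' Bands partition (partially) the displayed dPV/dCV positions into the
#' Periportal (PP), Mid-Zonal (MZ) and Pericentral (PC) measurement bands.
#' PP is a set of dPV positions, PC a set of dCV positions, and MZ may use
#' either metric.  Bands need not cover every position; vHPCs outside all
#' bands are labeled `"none"`.
#'
#' @param pp_dpv integer dPV positions of the PP band.
#' @param mz_dpv,mz_dcv integer dPV and/or dCV positions of the MZ band.
#' @param pc_dcv integer dCV positions of the PC band.
#' @return an object of class `band_config`.
#' @export
band_config <- function(pp_dpv, mz_dpv = integer(0), mz_dcv = integer(0),
                        pc_dcv = integer(0)) {
  bc <- structure(list(pp_dpv = as.integer(pp_dpv),
                       mz_dpv = as.integer(mz_dpv),
                       mz_dcv = as.integer(mz_dcv),
                       pc_dcv = as.integer(pc_dcv)),
                  class = "band_config")
  if (length(intersect(bc$pp_dpv, bc$mz_dpv)) ||
      length(intersect(bc$pc_dcv, bc$mz_dcv)))
    stop("band position ranges must be pairwise disjoint")
  bc
}

#' Assign PP / MZ / PC band labels to every vHPC position
#'
#' Deterministic given the graph and band configuration.  A position
#' matching more than one band under the configured ranges is a
#' configuration error (overlapping bands).
#'
#' @param graph a `lobule_graph` with zonal positions computed.
#' @param bands a [band_config()].
#' @return the graph with a `band` factor column (`PP`, `MZ`, `PC`,
#'   `none`) on `$vhpc`.
#' @export
assign_bands <- function(graph, bands) {
  stopifnot(inherits(graph, "lobule_graph"), inherits(bands, "band_config"))
  v <- graph$vhpc
  if (is.null(v$dPV)) stop("zonal positions must be computed first")
  in_pp <- v$dPV %in% bands$pp_dpv
  in_mz <- (v$dPV %in% bands$mz_dpv) | (v$dCV %in% bands$mz_dcv)
  in_pc <- v$dCV %in% bands$pc_dcv
  if (any(in_pp + in_mz + in_pc > 1L))
    stop("overlapping band ranges: some vHPC positions match several bands")
  band <- rep("none", nrow(v))
  band[in_pp] <- "PP"; band[in_mz] <- "MZ"; band[in_pc] <- "PC"
  v$band <- factor(band, levels = c("PP", "MZ", "PC", "none"))
  graph$vhpc <- v
  graph
}

#' Summarize structure statistics over sampled lobule graphs
#'
#' Computes the mean vHPC count, the mean count at every dPV and dCV
#' position, the fraction of vHPCs in the displayed position sets (dPV
#' 1-14; dCV 1-12 excluding positions already in the dPV set), and mean
#' band counts.  Fractions are ratios of across-graph means, matching how
#' the reference histograms are reported.
#'
#' @param graphs a list of `lobule_graph` objects (bands need not be
#'   assigned; `bands` is applied here).
#' @param bands a [band_config()].
#' @param dpv_display,dcv_display extents of the displayed dPV/dCV sets.
#' @return an object of class `structure_summary`.
#' @export
structure_summary <- function(graphs, bands,
                              dpv_display = 14L, dcv_display = 12L) {
  if (!length(graphs)) stop("at least one lobule graph is required")
  if (inherits(graphs, "lobule_graph")) graphs <- list(graphs)
  n <- length(graphs)
  max_dpv <- max(vapply(graphs, function(g) max(g$vhpc$dPV), numeric(1)))
  max_dcv <- max(vapply(graphs, function(g) max(g$vhpc$dCV), numeric(1)))
  dpv_counts <- numeric(max_dpv); dcv_counts <- numeric(max_dcv)
  total <- 0; n_dpv_set <- 0; n_dcv_excl <- 0
  band_sum <- c(PP = 0, MZ = 0, PC = 0, none = 0)
  for (g in graphs) {
    g <- assign_bands(g, bands)
    v <- g$vhpc
    total <- total + sum(v$count)
    dpv_counts <- dpv_counts +
      vapply(seq_len(max_dpv), function(d) sum(v$count[v$dPV == d]), numeric(1))
    dcv_counts <- dcv_counts +
      vapply(seq_len(max_dcv), function(d) sum(v$count[v$dCV == d]), numeric(1))
    in_dpv <- v$dPV <= dpv_display
    n_dpv_set <- n_dpv_set + sum(v$count[in_dpv])
    n_dcv_excl <- n_dcv_excl + sum(v$count[!in_dpv & v$dCV <= dcv_display])
    bs <- tapply(v$count, v$band, sum, default = 0)
    band_sum <- band_sum + bs[names(band_sum)]
  }
  mean_total <- total / n
  structure(list(
    n_graphs = n,
    mean_total_vhpc = mean_total,
    dpv_mean_counts = dpv_counts / n,
    dcv_mean_counts = dcv_counts / n,
    frac_dpv_display = 100 * (n_dpv_set / n) / mean_total,
    frac_dcv_display_excl = 100 * (n_dcv_excl / n) / mean_total,
    frac_combined = 100 * ((n_dpv_set + n_dcv_excl) / n) / mean_total,
    band_mean_counts = band_sum / n,
    dpv_display = dpv_display, dcv_display = dcv_display
  ), class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat("Lobule structure summary over", x$n_graphs, "sampled graphs\n")
  cat(sprintf("  mean vHPCs per lobule: %.0f\n", x$mean_total_vhpc))
  cat(sprintf("  dPV 1-%d: %.1f%%   dCV 1-%d (excl.): %.1f%%   combined: %.1f%%\n",
              x$dpv_display, x$frac_dpv_display,
              x$dcv_display, x$frac_dcv_display_excl, x$frac_combined))
  b <- x$band_mean_counts
  cat(sprintf("  band means  PP: %.0f  MZ: %.0f  PC: %.0f  (unbanded: %.0f)\n",
              b["PP"], b["MZ"], b["PC"], b["none"]))
  invisible(x)
}

#' Serialize a lobule graph to JSON
#'
#' @param graph a `lobule_graph`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
lobule_graph_to_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "lobule_graph"))
  js <- jsonlite::toJSON(list(nodes = graph$nodes, edges = graph$edges,
                              vhpc = graph$vhpc,
                              layer_mean_length = graph$meta$layer_mean_length,
                              seed = graph$meta$seed),
                         dataframe = "columns", digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Convert a lobule graph to an igraph object (for GraphML export)
#'
#' Requires the suggested `igraph` package.
#' @param graph a `lobule_graph`.
#' @return an `igraph` directed graph with PV and CV as terminal vertices.
#' @export
as_igraph_lobule <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for GraphML export")
  n <- nrow(graph$nodes)
  vn <- c("PV", as.character(graph$nodes$node), "CV")
  el <- cbind(ifelse(graph$edges$from == 0L, "PV", as.character(graph$edges$from)),
              ifelse(graph$edges$to == n + 1L, "CV", as.character(graph$edges$to)))
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  lay <- c(0L, graph$nodes$layer, 4L)[match(igraph::V(ig)$name, vn)]
  igraph::V(ig)$layer <- lay
  ig
}
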