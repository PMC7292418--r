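# Deterministic fixture generation: every module is testable without
# external data.

#' Generate a deterministic test fixture
#'
#' Three kinds are available:
#' \describe{
#'   \item{`tiny_lobule`}{a degenerate one-node-per-layer lobule graph
#'     with fixed dimensions (a 3-segment PV-to-CV chain) for transport
#'     tests.}
#'   \item{`single_vhpc`}{a scripted NAPQI arrival schedule (data.frame
#'     `cycle`, `n_arrivals`) that feeds both the enumeration oracle and
#'     the simulated single-vHPC chain.}
#'   \item{`synthetic_plasma_table`}{a synthetic per-animal plasma-ALT
#'     table: 18 animals measured once at 3, 4.5 or 6 h, generated from
#'     the linear scaling model with known per-animal skew factors
#'     delta_i applied to a synthetic sigmoid Body-ALT profile.  Used for
#'     exact delta-recovery tests; it is not mouse data.}
#' }
#'
#' @param kind one of `"tiny_lobule"`, `"single_vhpc"`,
#'   `"synthetic_plasma_table"`.
#' @param seed integer seed (fixtures are identical for a fixed seed).
#' @param dir optional directory; if given, fixture files are written as
#'   plain text (JSON / CSV) and paths are returned in the result.
#' @param deltas for the plasma table: vector of 18 known skew factors;
#'   default draws them i.i.d. lognormal(meanlog 0, sdlog 0.3).
#' @param scaling a [scaling_params()] used to generate plasma values.
#' @return the fixture object (see Details), invisibly with file paths
#'   attached when `dir` is given.
#' @export
generate_fixture <- function(kind = c("tiny_lobule", "single_vhpc",
                                      "synthetic_plasma_table"),
                             seed = 1L, dir = NULL, deltas = NULL,
                             scaling = scaling_params()) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  out <- switch(kind,
    tiny_lobule = {
      cfg <- lobule_config(layers = list(
        list(n_nodes = c(1L, 1L), circumference = c(4L, 4L), core_length = c(3L, 3L)),
        list(n_nodes = c(1L, 1L), circumference = c(4L, 4L), core_length = c(3L, 3L)),
        list(n_nodes = c(1L, 1L), circumference = c(4L, 4L), core_length = c(3L, 3L))),
        fanout = c(1L, 1L), n_lobules_per_liver = 1L)
      g <- sample_lobule_graph(cfg, seed = seed)
      if (!is.null(dir))
        lobule_graph_to_json(g, file.path(dir, "tiny_lobule.json"))
      g
    },
    single_vhpc = {
      sched <- data.frame(cycle = c(0L, 2L, 4L), n_arrivals = c(2L, 1L, 1L))
      if (!is.null(dir))
        utils::write.csv(sched, file.path(dir, "single_vhpc_schedule.csv"),
                         row.names = FALSE)
      sched
    },
    synthetic_plasma_table = {
      if (is.null(deltas)) deltas <- stats::rlnorm(18L, 0, 0.3)
      if (length(deltas) != 18L) stop("exactly 18 animals are generated")
      times <- rep(c(3, 4.5, 6), each = 6L)
      cycles <- as.integer(times * 3600)
      # synthetic sigmoid Body-ALT profile (objects), plateau ~ 1200
      tt <- seq_len(21600L)
      body_alt <- 1200 / (1 + exp(-(tt - 9000) / 2200))
      y <- deltas * scaling$S * body_alt[cycles]
      plasma <- data.frame(animal_id = sprintf("m%02d", 1:18),
                           time_h = times, alt_iu_ml = y)
      fx <- list(plasma = plasma, body_alt = body_alt, deltas = deltas)
      if (!is.null(dir)) {
        utils::write.csv(plasma, file.path(dir, "synthetic_plasma.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(cycle = tt, body_alt = body_alt),
                         file.path(dir, "synthetic_body_alt.csv"),
                         row.names = FALSE)
      }
      fx
    })
  invisible(out)
}
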