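# Lobule graph sampling, zonal metrics, bands, structure summaries.

test_that("degenerate config yields an acyclic PV-to-CV chain with chain distances", {
  g <- sample_lobule_graph(unit_chain_lobule(), seed = 1)
  expect_equal(nrow(g$nodes), 3L)
  # PV (0) -> 1 -> 2 -> 3 -> CV (4)
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("0 1", "1 2", "2 3", "3 4"))
  # unit-length chain: dPV counts up from PV, dCV counts up from CV
  expect_equal(g$vhpc$dPV, 1:3)
  expect_equal(g$vhpc$dCV, 3:1)
  expect_true(all(g$vhpc$zone >= 0 & g$vhpc$zone <= 1))
})

test_that("sampling is deterministic for a fixed seed and fresh otherwise", {
  cfg <- small_lobule()
  g1 <- sample_lobule_graph(cfg, seed = 42)
  g2 <- sample_lobule_graph(cfg, seed = 42)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  g3 <- sample_lobule_graph(cfg, seed = 43)
  expect_false(identical(g1$nodes, g3$nodes) && identical(g1$edges, g3$edges))
})

test_that("invalid configuration ranges are rejected", {
  expect_error(lobule_config(layers = list(
    list(n_nodes = c(5L, 3L), circumference = c(4L, 6L), core_length = c(2L, 4L)),
    list(n_nodes = c(3L, 3L), circumference = c(4L, 5L), core_length = c(2L, 3L)),
    list(n_nodes = c(2L, 3L), circumference = c(4L, 5L), core_length = c(2L, 3L)))),
    "invalid range")
  # layer 3 can never have more SSs than layer 2: not biomimetic
  expect_error(lobule_config(layers = list(
    list(n_nodes = c(3L, 4L), circumference = c(4L, 6L), core_length = c(2L, 4L)),
    list(n_nodes = c(2L, 2L), circumference = c(4L, 5L), core_length = c(2L, 3L)),
    list(n_nodes = c(5L, 6L), circumference = c(4L, 5L), core_length = c(2L, 3L)))),
    "not biomimetic")
  expect_error(lobule_config(layers = default_lobule_config()$layers,
                             hepatocyte_occupancy = 0), "hepatocyte_occupancy")
})

test_that("every sampled graph is layered-acyclic with full PV-CV connectivity", {
  cfg <- default_lobule_config()
  for (s in 1:5) {
    g <- sample_lobule_graph(cfg, seed = s)
    internal <- g$edges[g$edges$from != 0L & g$edges$to != nrow(g$nodes) + 1L, ]
    expect_true(all(g$nodes$layer[internal$to] ==
                      g$nodes$layer[internal$from] + 1L))
    expect_true(all(seq_len(nrow(g$nodes)) %in% g$edges$from))
    expect_true(all(seq_len(nrow(g$nodes)) %in% g$edges$to))
    expect_true(all(g$vhpc$dPV >= 1L), all(g$vhpc$dCV >= 1L))
    # layer 2 >= layer 3 node count in every sample
    expect_gte(sum(g$nodes$layer == 2L), sum(g$nodes$layer == 3L))
  }
})

test_that("band assignment is deterministic and anchored at the vein faces", {
  g <- sample_lobule_graph(default_lobule_config(), seed = 7)
  g <- assign_bands(g, default_band_config())
  v <- g$vhpc
  expect_true(all(v$band[v$dPV == 1L] == "PP"))
  expect_true(all(v$band[v$dCV == 1L] == "PC"))
  expect_true(all(levels(v$band) == c("PP", "MZ", "PC", "none")))
  g2 <- assign_bands(g, default_band_config())
  expect_identical(g$vhpc$band, g2$vhpc$band)
})

test_that("overlapping band ranges are a configuration error", {
  expect_error(band_config(pp_dpv = 1:4, mz_dpv = 4:6, pc_dcv = 1:3),
               "disjoint")
  # dPV/dCV cross-metric overlap caught at assignment
  g <- sample_lobule_graph(unit_chain_lobule(), seed = 1)
  expect_error(assign_bands(g, band_config(pp_dpv = 1:3, pc_dcv = 1:3)),
               "overlapping")
})

test_that("structure_summary on a degenerate chain is total or nothing per band", {
  g <- sample_lobule_graph(unit_chain_lobule(), seed = 1)
  s <- structure_summary(list(g), band_config(pp_dpv = 1L, pc_dcv = 1L))
  expect_equal(s$n_graphs, 1L)
  total <- s$mean_total_vhpc
  expect_true(all(s$band_mean_counts %in% c(0, total) |
                    s$band_mean_counts <= total))
  expect_equal(sum(s$dpv_mean_counts), total)
  expect_equal(s$frac_combined, 100)
  expect_error(structure_summary(list(), default_band_config()), "at least one")
})

test_that("default structure reproduces the calibrated reference statistics", {
  graphs <- lapply(1:20, function(i)
    sample_lobule_graph(default_lobule_config(), seed = 100 + i))
  s <- structure_summary(graphs, default_band_config())
  expect_lt(abs(s$mean_total_vhpc - 16165) / 16165, 0.05)
  expect_lt(abs(s$frac_dpv_display - 85.3), 3)
  expect_lt(abs(s$frac_dcv_display_excl - 14.1), 3)
  expect_lt(abs(s$band_mean_counts[["PP"]] - 4772) / 4772, 0.10)
  expect_lt(abs(s$band_mean_counts[["MZ"]] - 1721) / 1721, 0.10)
  expect_lt(abs(s$band_mean_counts[["PC"]] - 906) / 906, 0.10)
  # right skew of PV-to-CV distances: mean exceeds median
  dpv <- unlist(lapply(graphs, function(g) rep(g$vhpc$dPV, g$vhpc$count)))
  expect_gt(mean(dpv), stats::median(dpv))
})

test_that("structure summaries are reproducible for fixed seeds", {
  gs1 <- lapply(1:6, function(i) sample_lobule_graph(default_lobule_config(), i))
  gs2 <- lapply(1:6, function(i) sample_lobule_graph(default_lobule_config(), i))
  s1 <- structure_summary(gs1, default_band_config())
  s2 <- structure_summary(gs2, default_band_config())
  expect_identical(s1$dpv_mean_counts, s2$dpv_mean_counts)
  expect_identical(s1$band_mean_counts, s2$band_mean_counts)
})

test_that("graph serialization round-trips through JSON deterministically", {
  g <- sample_lobule_graph(small_lobule(), seed = 3)
  j1 <- lobule_graph_to_json(g)
  j2 <- lobule_graph_to_json(sample_lobule_graph(small_lobule(), seed = 3))
  expect_identical(as.character(j1), as.character(j2))
})
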