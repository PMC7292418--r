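# Whole-trial engine: determinism, conservation ledgers, cross-mechanism
# identities, the Marker internal standard, and an exactly computable
# deterministic timeline.

test_that("a trial is bit-identical for a fixed config and seed", {
  cfg <- small_cfg()
  l1 <- run_trial(cfg, trial_seed = 5, check_every = 0L)
  l2 <- run_trial(cfg, trial_seed = 5, check_every = 0L)
  expect_identical(l1$body, l2$body)
  expect_identical(l1$events, l2$events)
  expect_identical(l1$amounts, l2$amounts)
  expect_identical(l1$trig_cycle, l2$trig_cycle)
})

test_that("zero dose produces no events and no Body ALT", {
  cfg <- small_cfg(dose = 0L, duration = 400L)
  log <- run_trial(cfg, trial_seed = 1, check_every = 100L)
  expect_true(all(log$events == 0L))
  expect_true(all(log$body[, "ALT"] == 0))
  expect_true(all(log$body[, c("APAP", "G", "S")] == 0))
})

test_that("doses above the object cap are rejected by the engine", {
  cfg <- small_cfg()
  cfg$dose_objects <- 150000L   # bypass the constructor check on purpose
  expect_error(run_trial(cfg, 1), "100,000")
})

test_that("object ledgers close at every cycle of a checked run", {
  cfg <- small_cfg(dose = 3000L, duration = 800L)
  # check_every = 1: the engine hard-fails on any per-kind ledger violation
  expect_no_error(run_trial(cfg, trial_seed = 3, check_every = 1L))
})

test_that("Body ALT is monotone non-decreasing over the run", {
  for (mode in c("MITOD", "NECROTIC_ONLY")) {
    log <- run_trial(small_cfg(mode, dose = 3000L, duration = 1500L), 2,
                     check_every = 0L)
    expect_true(all(diff(log$body[, "ALT"]) >= 0))
  }
})

test_that("disposition and damage series are bit-identical across the four release modes", {
  logs <- lapply(c("NECROTIC_ONLY", "MITOD", "NONMD", "DUAL"), function(m)
    run_trial(small_cfg(m, dose = 3000L, duration = 1500L), trial_seed = 9,
              check_every = 0L))
  ref <- logs[[1]]
  for (l in logs[-1]) {
    expect_identical(l$body[, c("APAP", "G", "S")],
                     ref$body[, c("APAP", "G", "S")])
    dmg_cols <- grep("napqi|mitoD|nonMD|apap_cell", colnames(l$amounts))
    expect_identical(l$amounts[, dmg_cols], ref$amounts[, dmg_cols])
    expect_identical(l$trig_cycle, ref$trig_cycle)
    expect_identical(l$necrotic_cycle, ref$necrotic_cycle)
    expect_identical(l$events[, "liver.necrosis_triggered"],
                     ref$events[, "liver.necrosis_triggered"])
  }
})

test_that("the Marker body curve is invariant to mechanism parameter changes", {
  base <- small_cfg("MITOD", dose = 3000L, duration = 1500L)
  alt1 <- small_cfg("NECROTIC_ONLY", dose = 3000L, duration = 1500L)
  alt2 <- small_cfg("MITOD", dose = 3000L, duration = 1500L)
  alt2$mechanism <- mechanism_config(release_mode = "MITOD",
                                     leakage_threshold = 5L,
                                     leak_lag_cycles = c(4300L, 19600L),
                                     death_delay_cycles = c(8800L, 23200L))
  m0 <- run_trial(base, 4, check_every = 0L)$body[, "Marker"]
  m1 <- run_trial(alt1, 4, check_every = 0L)$body[, "Marker"]
  m2 <- run_trial(alt2, 4, check_every = 0L)$body[, "Marker"]
  expect_identical(m0, m1)
  expect_identical(m0, m2)
})

test_that("total ALT release respects the per-vHPC initial amount", {
  cfg <- small_cfg("MITOD", dose = 4000L, duration = 2000L)
  log <- run_trial(cfg, 6, check_every = 0L, return_state = TRUE)
  released <- log$cum_released_leak + log$cum_released_necrotic
  expect_lte(released, 5 * log$n_vhpc)
  # per-vHPC counter identity: released + remaining == 5 * n
  expect_equal(released + sum(log$state$alt_counter), 5 * log$n_vhpc)
})

test_that("trigger-to-necrotic delays lie within the configured [min, max)", {
  cfg <- small_cfg("MITOD", dose = 4000L, duration = 12000L)
  cfg$mechanism <- mechanism_config(release_mode = "MITOD",
                                    leak_lag_cycles = c(100L, 200L),
                                    death_delay_cycles = c(500L, 900L))
  log <- run_trial(cfg, 8, check_every = 0L)
  done <- log$necrotic_cycle >= 0L
  expect_gt(sum(done), 0L)
  delays <- log$necrotic_cycle[done] - log$trig_cycle[done]
  expect_true(all(delays >= 500L & delays < 900L))
})

test_that("leakage makes cumulative ALT release dominate the necrotic-only path", {
  # shared damage trajectory (same seed/substreams): leakage adds earlier
  # releases and the necrotic remainder is common
  nec <- run_trial(small_cfg("NECROTIC_ONLY", dose = 4000L, duration = 9000L),
                   11, check_every = 0L)
  mit <- run_trial(small_cfg("MITOD", dose = 4000L, duration = 9000L),
                   11, check_every = 0L)
  expect_true(all(mit$events[, "liver.alt_released"] >=
                    nec$events[, "liver.alt_released"]))
})

test_that("a fully determined parameterization reproduces its exact event timeline", {
  # one vHPC per segment on a unit chain; all probabilities 0 or 1
  lob <- unit_chain_lobule()
  flow <- flow_params(dose_transfer_fraction = 1, downstream_prob = 1,
                      entry_prob = 1, exit_prob = 0, ec_bind_prob = 0,
                      ec_release_prob = 0, hpc_bind_prob = 0,
                      hpc_release_prob = 0)
  grads <- gradient_set(p_metabolism = c(1 - 1e-12, 1),
                        p_napqi = c(1 - 1e-12, 1),
                        gsh_threshold = c(1e-9, 0),
                        p_mitigate_mitod = c(1e-12, 0),
                        p_mitigate_nonmd = c(0, 1e-12),
                        p_mito_fraction = 1)
  mech <- mechanism_config(release_mode = "MITOD",
                           napqi_removal_prob = 1,
                           amplification_range = c(3L, 3L),
                           leak_lag_cycles = c(5L, 6L),
                           death_delay_cycles = c(10L, 11L))
  cfg <- vexperiment_config(lobule = lob, flow = flow, gradients = grads,
                            mechanism = mech,
                            bands = band_config(pp_dpv = 1L, pc_dcv = 1L),
                            dose_objects = 10L, marker_fraction = 0,
                            duration_cycles = 40L, n_trials = 1L,
                            n_lobules = 1L)
  log <- run_trial(cfg, trial_seed = 1, thin = 1L, check_every = 1L,
                   return_state = TRUE)
  # cycle 0: dose -> segment 1 -> segment 2; all 10 APAP enter the middle
  # cell, are metabolized to NAPQI and removed: 1 removal depletes GSH,
  # 9 removals x (3+1) = 36 MitoD -> leakage + necrosis trigger at t = 0
  mid <- 2L
  expect_equal(log$trig_cycle[mid], 0L)
  expect_equal(log$leak_cycle[mid], 0L)
  expect_equal(unname(log$events[1, "liver.gsh_depleted"]), 1L)
  expect_equal(log$state$mitoD[mid], 36L)
  # one release scheduled per cycle at lag 5 until all 5 ALT are scheduled;
  # releases fire at t = 5..9; necrotic at t = 10 with nothing left
  expect_equal(unname(log$events[5, "liver.alt_scheduled"]), 5L)
  expect_equal(unname(log$events[10, "liver.alt_released"]), 5L)
  expect_equal(log$necrotic_cycle[mid], 10L)
  expect_equal(log$state$alt_counter[mid], 0L)
  # released ALT takes two downstream hops: Body ALT steps up over
  # t = 7..11 (log row t + 1)
  expect_equal(unname(log$body[8:13, "ALT"]), c(1, 2, 3, 4, 5, 5))
  expect_equal(unname(log$body[40, "ALT"]), 5)
})

test_that("measurement extraction matches the recorded series", {
  cfg <- small_cfg(dose = 2000L, duration = 600L)
  log <- run_trial(cfg, 3, thin = 60L, check_every = 0L)
  rec <- measurement_at(log, 300L)
  expect_equal(rec$body, log$body[300L, ])
  expect_equal(rec$events, log$events[300L, ])
  expect_error(measurement_at(log, 10000L), "out of range")
})

test_that("mean Necrotic count at 6 h is non-decreasing in Dose", {
  necrotic_6h <- function(dose) {
    cfg <- default_vexperiment_config(dose_objects = dose, n_lobules = 1L,
                                      n_trials = 3L, master_seed = 55L)
    res <- run_vexperiment(cfg, thin = 7200L, check_every = 0L)
    unname(res$events_mean[21600L, "liver.necrotic"])
  }
  counts <- vapply(c(25000L, 50000L, 100000L), necrotic_6h, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[1], 0)
})
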