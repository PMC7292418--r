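# Per-vHPC event logic: metabolism, NAPQI removal, mitigation, necrosis,
# the four leakage modes, and the ALT-counter identity.

pc_cell <- function(grad = gradient_set()) hepatocyte_state(zone = 1, grad)

test_that("metabolism conserves APAP into exactly one product", {
  g <- gradient_set()
  g$p_metabolism <- list(z = c(0, 1), v = c(1, 1) - 1e-12)
  g$p_napqi <- list(z = c(0, 1), v = c(1, 1) - 1e-12)
  h <- pc_cell(g)
  h$apap_free <- 1L
  set.seed(1)
  h <- metabolize_step(h, g)
  expect_equal(h$apap_free, 0L)
  expect_equal(h$napqi, 1L)
  expect_equal(h$g + h$s, 0L)
})

test_that("non-NAPQI metabolites split equally between G and S in expectation", {
  g <- gradient_set()
  g$p_metabolism <- list(z = c(0, 1), v = c(1, 1) - 1e-12)
  g$p_napqi <- list(z = c(0, 1), v = c(1e-12, 2e-12))
  h <- pc_cell(g)
  h$apap_free <- 40000L
  set.seed(2)
  h <- metabolize_step(h, g)
  expect_equal(h$napqi, 0L)
  expect_equal(h$g + h$s, 40000L)
  # two-sided binomial check at p = 0.5
  expect_gt(stats::binom.test(h$g, 40000L, 0.5)$p.value, 1e-4)
})

test_that("default gradients have the stated zonal monotonicities", {
  g <- gradient_set()
  expect_gt(grad_value(g$p_metabolism, 1), grad_value(g$p_metabolism, 0))
  expect_gt(grad_value(g$p_napqi, 1), grad_value(g$p_napqi, 0))
  expect_lt(grad_value(g$gsh_threshold, 1), grad_value(g$gsh_threshold, 0))
  expect_gt(grad_value(g$p_mitigate_mitod, 0), grad_value(g$p_mitigate_mitod, 1))
  expect_gt(grad_value(g$p_mitigate_nonmd, 1), grad_value(g$p_mitigate_nonmd, 0))
})

test_that("NAPQI removal depletes GSH first, then creates amplified bursts", {
  mech <- mechanism_config(napqi_removal_prob = 1,
                           amplification_range = c(3L, 3L))
  g <- gradient_set(p_mito_fraction = 1)
  h <- pc_cell(g)
  h$gsh_counter <- 2
  h$napqi <- 1L
  set.seed(3)
  h <- napqi_removal_step(h, mech, g)
  expect_equal(h$gsh_counter, 1)
  expect_equal(h$mitoD + h$nonMD, 0L)
  # at zero GSH a removal yields n + 1 = 4 products of a single type
  h$gsh_counter <- 0
  h$napqi <- 1L
  h <- napqi_removal_step(h, mech, g)
  expect_equal(h$mitoD, 4L)
  expect_equal(h$nonMD, 0L)
})

test_that("post-depletion removal probability is one half per cycle", {
  mech <- mechanism_config()
  g <- gradient_set()
  set.seed(4)
  removed <- replicate(3000, {
    h <- pc_cell(g); h$gsh_counter <- 0; h$napqi <- 1L
    h <- napqi_removal_step(h, mech, g)
    h$napqi == 0L
  })
  expect_gt(stats::binom.test(sum(removed), 3000, 0.5)$p.value, 1e-4)
})

test_that("amplification draws cover the closed integer range", {
  mech <- mechanism_config(napqi_removal_prob = 1)
  g <- gradient_set(p_mito_fraction = 1)
  set.seed(5)
  sizes <- replicate(600, {
    h <- pc_cell(g); h$gsh_counter <- 0; h$napqi <- 1L
    napqi_removal_step(h, mech, g)$mitoD
  })
  expect_setequal(sort(unique(sizes)), 4:7)   # n in {3..6}, products n + 1
})

test_that("mitigation removes at most one product per type per cycle", {
  g <- gradient_set()
  g$p_mitigate_mitod <- list(z = c(0, 1), v = c(1, 1) - 1e-12)
  h <- pc_cell(g); h$zone <- 0
  h$mitoD <- 3L
  set.seed(6)
  h <- mitigation_step(h, g)
  expect_equal(h$mitoD, 2L)
  g$p_mitigate_mitod <- list(z = c(0, 1), v = c(1e-12, 0))
  g$p_mitigate_nonmd <- list(z = c(0, 1), v = c(0, 1e-12))
  h$nonMD <- 5L
  h2 <- mitigation_step(h, g)
  expect_equal(h2$mitoD, h$mitoD)
  expect_equal(h2$nonMD, h$nonMD)
})

test_that("necrosis triggers strictly above threshold with a bounded death delay", {
  mech <- mechanism_config()
  h <- pc_cell()
  h$mitoD <- 4L                              # at threshold: no trigger
  h <- necrosis_step(h, mech, t = 100L)
  expect_false(h$necrosis_triggered)
  h$mitoD <- 5L
  set.seed(7)
  h <- necrosis_step(h, mech, t = 100L)
  expect_true(h$necrosis_triggered)
  delay <- h$necrotic_due_cycle - 100L
  expect_gte(delay, 7200L)
  expect_lt(delay, 21600L)
})

test_that("the necrotic transition externalizes all remaining ALT at once", {
  mech <- mechanism_config()
  h <- pc_cell()
  h$necrosis_triggered <- TRUE
  h$necrotic_due_cycle <- 500L
  h$alt_counter <- 3L
  h <- necrosis_step(h, mech, t = 499L)
  expect_false(h$necrotic)
  h <- necrosis_step(h, mech, t = 500L)
  expect_true(h$necrotic)
  expect_equal(h$last_externalized, 3L)
  expect_equal(h$alt_counter, 0L)
  # absorbing: no further events
  h$mitoD <- 100L
  h2 <- necrosis_step(h, mech, t = 501L)
  expect_identical(h2$released, h$released)
})

test_that("leakage trigger tests follow the release mode", {
  t <- 10L
  base <- function() { h <- pc_cell(); h }
  trig <- function(mode, mitoD, nonMD, dual = "sum") {
    mech <- mechanism_config(release_mode = mode, dual_semantics = dual)
    h <- base(); h$mitoD <- mitoD; h$nonMD <- nonMD
    leakage_step(h, mech, t)$leakage_triggered
  }
  set.seed(8)
  expect_true(trig("MITOD", 2L, 0L))         # threshold 1, strict >
  expect_false(trig("MITOD", 1L, 0L))
  expect_false(trig("NONMD", 10L, 0L))
  expect_true(trig("NONMD", 0L, 2L))
  expect_true(trig("DUAL", 1L, 1L, "sum"))   # 1 + 1 > 1
  expect_false(trig("DUAL", 1L, 1L, "both")) # each must exceed 1
  expect_true(trig("DUAL", 2L, 2L, "both"))
  # Necrotic-only: leakage is a no-op
  mech <- mechanism_config(release_mode = "NECROTIC_ONLY")
  h <- base(); h$mitoD <- 100L
  h <- leakage_step(h, mech, t)
  expect_false(h$leakage_triggered)
  expect_length(h$pending, 0L)
})

test_that("scheduling is bounded by unscheduled ALT and lags are in range", {
  mech <- mechanism_config(release_mode = "MITOD")
  h <- pc_cell()
  h$mitoD <- 10L
  set.seed(9)
  for (t in 0:9) h <- leakage_step(h, mech, t)
  expect_equal(length(h$pending), 5L)        # one per cycle, capped at ALT
  lags <- h$pending - 0:4
  expect_true(all(lags >= 2700L & lags < 18000L))
})

test_that("falling below threshold clears the trigger but scheduled releases persist and fire", {
  mech <- mechanism_config(release_mode = "MITOD",
                           leak_lag_cycles = c(5L, 6L),
                           death_delay_cycles = c(10L, 11L))
  h <- pc_cell()
  h$mitoD <- 2L
  set.seed(10)
  h <- leakage_step(h, mech, t = 0L)         # triggers, schedules one at t=5
  expect_true(h$leakage_triggered)
  expect_equal(h$pending, 5L)
  h$mitoD <- 0L
  h <- leakage_step(h, mech, t = 1L)
  expect_false(h$leakage_triggered)
  expect_true(h$ever_leak_triggered)
  expect_equal(h$pending, 5L)                # persists
  for (t in 2:5) h <- leakage_step(h, mech, t)
  expect_equal(h$released, 1L)
  expect_equal(h$alt_counter, 4L)
  expect_length(h$pending, 0L)
})

test_that("per-vHPC released + counter identity holds through random histories", {
  mech <- mechanism_config(release_mode = "MITOD",
                           leak_lag_cycles = c(3L, 30L),
                           death_delay_cycles = c(40L, 80L))
  g <- gradient_set()
  set.seed(11)
  for (rep in 1:10) {
    h <- pc_cell(g)
    h$gsh_counter <- 1
    for (t in 0:300) {
      if (t %% 7 == 0) h$napqi <- h$napqi + 1L
      h <- napqi_removal_step(h, mech, g)
      h <- mitigation_step(h, g)
      h <- necrosis_step(h, mech, t)
      rel_n <- h$last_externalized
      h <- leakage_step(h, mech, t)
      expect_equal(h$released + h$alt_counter, 5L)
    }
    expect_lte(h$released, 5L)
  }
})

test_that("futile cycle conserves APAP + pAP and is inert when disabled", {
  h <- pc_cell()
  h$apap_free <- 2L
  h0 <- futile_cycle_step(h, 1, 0, enabled = FALSE)
  expect_identical(h0$apap_free, 2L)
  expect_identical(h0$pap, 0L)
  set.seed(12)
  h1 <- futile_cycle_step(h, 0, 0, enabled = TRUE)
  expect_identical(h1$apap_free, 2L)
  h2 <- futile_cycle_step(h, 1, 0, enabled = TRUE)
  expect_equal(h2$apap_free, 0L)
  expect_equal(h2$pap, 2L)
  expect_equal(h2$apap_free + h2$pap, 2L)
})
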