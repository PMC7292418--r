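---
title: "A virtual liver for ALT biomarker release: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual liver for ALT biomarker release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaltsim)
```

## The scientific problem

Elevated plasma alanine aminotransferase (ALT) after an acetaminophen
(APAP) overdose is usually read as passive release from necrotic
hepatocytes, but the release mechanism itself cannot be observed in
vivo. `hepaltsim` builds a discrete-event, agent-based virtual mouse
liver in which four candidate release mechanisms — necrosis-only
release, leakage caused by mitochondrial damage, leakage caused by
non-mitochondrial damage, and a dual-cause variant — share one identical
toxicity model, so that differences in the simulated plasma-ALT curve
are attributable to the release mechanism alone.

This vignette documents the model and its assumptions, the parameters
that matter, the calibration that fixed the shipped defaults, the
numerical and design choices made where the design was genuinely open,
and the limitations of what simulated results can show.

## Model structure

### The lobule graph

A vLobule is a directed acyclic graph of Sinusoid Segments (SS) in three
layers; flow enters every layer-1 segment from the Portal Vein and exits
every layer-3 segment into the Central Vein. One upstream segment can
feed several downstream segments. Each segment is a quasi-3D grid
(circumference x core length, in grid points); vHPC agents occupy 90% of
the hepatocyte grid and vECs 99% of the endothelial grid. All per-layer
node counts and segment dimensions are sampled fresh at the start of
every execution, within the configured ranges, so each trial sees a
different (but statistically stationary) liver. A sampled graph always
satisfies: acyclicity, full PV-to-CV connectivity, and at least as many
segments in layer 2 as in layer 3.

A vHPC's position is summarized by two 1-based distances in core grid
points: `dPV` (rounded mean length of upstream layers plus its own core
position) and `dCV` (the symmetric distance from the CV). The normalized
zonal coordinate `z = dPV / (dPV + dCV)` is the argument of every
zonation gradient. Any strictly monotone alternative would serve; this
ratio was chosen because it is bounded in [0, 1] and symmetric in the
two distances.

### Measurement bands

Periportal (PP), Mid-Zonal (MZ) and Pericentral (PC) bands are sets of
dPV/dCV positions: by default PP = dPV 1–4, MZ = dCV 4–7 and
PC = dCV 1–3. Bands are partial covers — most mid-lobule positions are
unbanded — because the reference band counts sum to far less than the
total vHPC population; the cut points are a calibration product (see
below). Placing MZ on the dCV side (immediately upstream of PC) rather
than as a dPV window was a deliberate choice: a dPV window of equal
count would sit at z ≈ 0.25, which is periportal territory and would
contradict the expected mid-zonal damage ordering.

### Compound disposition

One simulation cycle maps to one second. Per cycle:

1. a binomially thinned fraction (default 0.005) of Body APAP (and of
   the Marker) transfers to the PV and spreads uniformly over layer-1
   segments;
2. every extracellular object independently advances one segment toward
   the CV with probability `downstream_prob` (objects reaching the CV
   join the Body the same cycle);
3. vEC binders bind and release extracellular APAP (bounded by vEC
   capacity); membrane-crossing compounds enter cells
   (`entry_prob`), and intracellular free APAP, G and S exit
   (`exit_prob`); intracellular binders sequester free APAP.

APAP recirculates: unmetabolized objects returning to the Body re-enter
the liver on later passes, which is what sustains pericentral exposure
over tens of minutes. The Marker is extracellular-only and non-binding
(a sucrose analog); ALT objects, once externalized, are
extracellular-only and never re-enter cells, and Body ALT is never
cleared. Metabolite (G, S) re-uptake by cells is neglected: they cross
outward only. Per-kind object ledgers are recomputed inside the engine
at configurable intervals and any violation aborts the trial with the
offending cycle — conservation is treated as a bug detector, not a
warning.

### Per-cell toxicodynamics

Each vHPC runs, per cycle: zonated metabolism (each free APAP
metabolized with probability `p_metabolism(z)`; the product is NAPQI
with probability `p_napqi(z)`, else G or S with equal probability);
NAPQI removal (each NAPQI removed with probability 0.5 per cycle — the
same value before and after glutathione depletion); GSH depletion (a
removal decrements the location-determined GSH counter by 1.0 while it
is positive; a counter of 0 maps to effective depletion); damage bursts
(each post-depletion removal creates `n + 1` products, `n` drawn
uniformly from the integers {3, …, 6}, all MitoD with probability
`p_mito_fraction`, else all nonMD); damage mitigation (at most one MitoD
and one nonMD removal per cycle, with zonated probabilities); necrosis
(MitoD strictly above 4 triggers the Necrosis-Triggered state and draws
a Death Delay uniformly from [7200, 21600) cycles; at the due cycle the
cell becomes Necrotic, externalizes all remaining ALT with zero delay
and performs no further events); and leakage (mode-dependent trigger
test against the ALT Leakage Threshold of 1, strict; while triggered,
one release is scheduled per cycle, bounded by unscheduled ALT, at a lag
uniform on [2700, 18000) cycles; scheduled releases fire iff the ALT
counter is positive and persist even if damage later falls below
threshold, which also clears the triggered state).

Every vHPC holds 5 ALT objects at t = 0, independent of location, so
`released + counter = 5` is an exact per-cell identity and total release
is bounded by five times the cell count.

The amplification draw is discrete uniform on {3, 4, 5, 6}: integer
products require integers, and the descriptions of the draw are
ambiguous about continuity, so the bracketed integers are used.

### The exLT variant

The extended-lag-time variant shifts both the leakage-lag and
death-delay distributions upward by 1600 cycles, giving
[4300, 19600) and [8800, 23200). One reported central value for the
shifted leakage distribution (a "median" of 2.875 h) is not the midpoint
of that interval; it is treated as a probable erratum and not
reproduced — the package reports the analytic mean of whatever interval
is configured.

## Random-number architecture

Each trial draws from four named xoshiro256++ substreams: *disposition*
(APAP/G/S transport, dosing, cell exchange), *marker* (Marker transport
only), *damage* (metabolism, NAPQI removal, bursts, mitigation, death
delays) and *release* (leakage lags and ALT transport). Consequences,
both verified by tests:

* swapping the release mechanism (or any leakage parameter) leaves the
  disposition and damage trajectories bit-identical, which makes the
  four mechanisms exactly comparable on a shared damage history and
  makes the leakage mechanisms' cumulative release dominate the
  necrosis-only path cycle by cycle;
* the Marker body-accumulation curve is invariant to every mechanism
  parameter at a fixed structure seed (the Marker substream also makes
  it invariant to dose changes, a strengthening that costs nothing).

Within a cycle, vHPCs are updated in index order rather than in a
shuffled order: updates are mutually independent within a cycle (no vHPC
reads another's state), so the update order cannot affect the joint
distribution, and skipping the per-cycle shuffle of ~65,000 indices
keeps the engine fast. Event types within a cell follow the causal
order: exchange, metabolism, removal, mitigation, necrotic transition,
trigger tests, releases.

Binomial draws use an exact sampler (Bernoulli loop for small n,
inversion for small n·p, halving recursion otherwise) so that ledgers
close exactly and deterministic parameterizations (probabilities 0 or 1)
consume no randomness, which the exact-timeline test exploits.

## Parameters and shipped defaults

Structural sampling ranges (per layer: node count, circumference, core
length) are free parameters: the printed sources do not pin them. They
were fixed once by a seeded search against the reference structural
statistics — a mean of ~16,165 vHPCs per lobule; dPV positions 1–14
holding ~85.3% of vHPCs and dCV 1–12 a further ~14.1%; right-skewed
PV-to-CV distances; band means near 4772 (PP), 1721 (MZ) and 906 (PC) —
followed by Monte-Carlo verification on held-out seed sets
(`calibrate_structure()` automates the same loop). Two stability
properties were imposed beyond the point statistics: every layer's mean
core length is an integer, so the per-lobule rounded layer offsets do
not flip between adjacent values (a half-integer mean makes band counts
bimodal across executions), and the cumulative dPV mass at the median
position carries a margin of several percentage points, so the
mean-exceeds-median skew property is stable under resampling.

Kinetic defaults are the flow probabilities
(`downstream_prob = 0.6`, `entry_prob = 0.18`, `exit_prob = 0.10`,
binder probabilities 0.03/0.05) and the gradient knots. Gradients are
piecewise linear in `z` with a default interior knot at `z = 0.7`;
single-segment linear gradients cannot concentrate NAPQI formation
pericentrally enough, whereas the two-segment defaults mirror the
strongly pericentral localization of CYP2E1. Defaults:

| gradient | z = 0 | z = 0.7 | z = 1 | direction |
|---|---|---|---|---|
| `p_metabolism` | 0.001 | 0.02 | 0.5 | increasing |
| `p_napqi` | 0.005 | 0.25 | 0.98 | increasing |
| `gsh_threshold` | 14 | 3 | 1 | decreasing |
| `p_mitigate_mitod` | 0.2 | 0.006 | 0.0005 | decreasing |
| `p_mitigate_nonmd` | 0.0005 | 0.05 | 0.2 | increasing |

with `p_mito_fraction = 0.65`. These were fixed by iterative
falsify-refine cycles against two pericentral timing statistics at the
medium dose — the median PC Necrosis-Trigger time (at most 40 minutes)
and the PC Leakage-Triggered fraction at 30 minutes (about 50%) — plus
the qualitative damage ordering (MitoD per vHPC PC > MZ > PP after 1 h;
pericentral nonMD below pericentral MitoD). Monotonicity of every
gradient is validated at construction, in the stated direction, over all
knots.

Dose maps linearly to objects (`objects = round(mg/kg × 500/3)`), so
150, 300 and 600 mg/kg give 25,000, 50,000 and 100,000 objects, with
100,000 as a hard cap. The dose-transfer fraction of 0.005 per cycle
makes absorption effectively complete within ~20 minutes, consistent
with early-phase dynamics at one-second resolution.

Problem sizes: a vLiver defaults to 12 lobules for structural work; the
kinetic default is a reduced vLiver of 4 lobules with 12 trials per
vExperiment (72 trials are recommended for small doses, where
between-trial variance grows). These sizes make a full vExperiment a
sub-minute computation while keeping ~65,000 cell agents per trial.

## Plasma scaling

Body ALT maps to plasma concentration as `Y_t = S·X_t + ε` with
`S = 1.72` IU ml⁻¹ per ALT object and, per animal,
`y_{i,t} = δ_i·(S·X_t + ε)`. The error term defaults to zero — the
individual random error cannot be separated from δ, so a Gaussian option
exists only for robustness studies. Each δ_i uses the animal's single
observation time (the reference design measures each mouse once, at 3,
4.5 or 6 h). `delta_summary()` reports mean, variance, SD and CV = s/x̄;
the Individualized Mapping Criterion passes when the mean δ is within
1.0 ± 0.1. The reported CV is defined as s/x̄ throughout; published
summary pairs are not exactly self-consistent on this point, and the
package simply states its definition rather than reverse-engineering
another.

The semiquantitative target-band check (`band_check()`) requires the
scaled curve to lie within a user-supplied [lower, upper] band (closed
intervals, linear interpolation between band knots), to be
non-decreasing, and to be "sigmoidal", operationalized as: the discrete
second difference of a moving-average-smoothed series (window 3 by
default) changes sign exactly once. The check is invariant to joint
rescaling of series and band. Band edges are figure-derived quantities
and must be supplied by the user; none are shipped.

## Open decisions, resolved

* **Dual-cause semantics.** One description compares the *sum* of the
  two damage pools to the Leakage Threshold; another requires *both*
  thresholds to be exceeded. Both are implemented
  (`dual_semantics = "sum"` or `"both"`); the default is `"sum"`, the
  description given in the more detailed methods text.
* **Leakage Threshold 1 vs 5.** The validated kinetic work uses 1; the
  dose-response exploration discusses 5 → 10. The default is 1 and the
  threshold is fully configurable, so the 5 → 10 experiment is a config
  change.
* **Scheduling multiplicity.** How many releases may be scheduled per
  triggered cycle is unstated; one per cycle (bounded by unscheduled
  ALT) is used, which spreads scheduling over several cycles in the way
  prolonged cumulative-scheduling curves suggest.
* **Pre-depletion removal probability.** The 0.5/cycle NAPQI removal
  probability is stated only for the post-depletion phase; the same
  value is used before depletion (configurable).
* **Necrotic cells and entry.** A Necrotic vHPC performs no further
  events and admits no compounds; objects that would have entered remain
  extracellular. Its residual intracellular contents stay frozen and
  remain on the conservation ledger.

## The synthetic plasma fixture

`generate_fixture("synthetic_plasma_table")` emulates the *structure* of
an individualized plasma-ALT data set — 18 animals, six each at 3, 4.5
and 6 h, one observation per animal — by applying known δ_i to a
synthetic sigmoid Body-ALT profile. It is labeled synthetic and is not
mouse data: it exercises the estimation and criterion machinery (exact
δ recovery when ε = 0, criterion pass rates under lognormal δ), nothing
more. Passing those tests shows the scaling layer is self-consistent; it
says nothing about agreement with any real animal.

## What passing tests do and do not show

The test suite and the acceptance script establish: structural
statistics of sampled livers match the calibration targets; object
conservation and the ALT counter identity hold exactly; delays fall in
their configured intervals; the four mechanisms share bit-identical
damage histories; a single-cell necrosis-trigger-time distribution
matches an exhaustive Markov-chain enumeration (total-variation distance
at most 0.05 at 10,000 replicates); pericentral trigger timing and the
30-minute leakage fraction fall in their calibrated ranges; and the mean
Necrotic count at 6 h increases with dose. They do **not** show that any
mechanism reproduces real mouse plasma-ALT values: that comparison
requires per-animal data and figure-derived target bands that are not
shipped, and must be supplied by the user through
`estimate_delta_table()` and `band_check()`.

## Known limitations

* A vHPC does not map 1:1 to a hepatocyte, and the quasi-3D segment grid
  is not literal sinusoid anatomy; events, not structures, carry the
  analogy.
* No GSH resynthesis, no ALT plasma clearance, and no regeneration or
  proliferation — the model is built for the first ~6–12 h post-dose.
* The movement kernel (one biased step per cycle at segment granularity)
  and the dose-transfer fraction are stand-ins; any
  conservation-preserving kernel with PV-to-CV drift is conformant and
  both are configurable.
* Extracellular compounds are pooled per segment, so in-band
  extracellular ALT is attributed through each segment's majority band
  rather than per grid position.
* The single calibrated default cannot explain low- and high-dose
  plasma ALT simultaneously; dose-dependent thresholds or lag
  distributions are left as configuration hooks, not mechanisms.
* The APAP ⟷ p-aminophenol futile cycle is reduced to an optional
  probabilistic toggle, disabled by default.
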