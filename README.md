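# hepaltsim

Discrete-event Monte Carlo simulation of acetaminophen (APAP)
hepatotoxicity in a virtual mouse liver, with competing mechanisms of
alanine aminotransferase (ALT) biomarker release.

Plasma ALT is the standard clinical biomarker of liver injury, and its
interpretation usually assumes passive release from dying cells. This
package implements an agent-based virtual liver in which that assumption
can be challenged: hepatocyte agents (vHPCs) on Monte-Carlo-sampled
hepatic lobule graphs metabolize APAP along periportal-to-pericentral
(PP-to-PC) zonation gradients, deplete glutathione (GSH), accumulate and
mitigate two classes of damage products, and externalize ALT under four
competing release mechanisms that can be swapped without touching the
underlying toxicity model:

| Mechanism | ALT is released |
|---|---|
| `NECROTIC_ONLY` | only when a cell transitions to the Necrotic state |
| `MITOD` (MitoD-Caused) | after mitochondrial damage exceeds the ALT Leakage Threshold, plus necrotic release |
| `NONMD` (nonMD-Caused) | after non-mitochondrial damage exceeds the threshold, plus necrotic release |
| `DUAL` (Dual-Cause) | after combined damage exceeds the threshold, plus necrotic release |

It is intended for quantitative systems toxicology researchers who want
to explore how zonated cellular damage, lag-time distributions, and
lobular structure jointly shape a plasma biomarker curve.

## The model in brief

* **Structure.** A vLobule is a three-layer directed acyclic graph of
  Sinusoid Segments running Portal Vein (PV) to Central Vein (CV). Every
  segment's grid dimensions are Monte-Carlo sampled per execution; vHPCs
  occupy 90% of the hepatocyte grid. Each vHPC has distances dPV and dCV
  (in core grid points) and a zonal coordinate `z = dPV / (dPV + dCV)`.
  Periportal, Mid-Zonal and Pericentral measurement bands are position
  sets on dPV/dCV.
* **Disposition.** One cycle maps to one second. Each cycle a fraction
  of Body APAP transfers to the PV; discrete compound objects percolate
  stochastically toward the CV, enter and exit cells, exchange with
  non-specific binders, and return to the Body from the CV. An inert
  extracellular Marker (a sucrose analog) is co-dosed as an internal
  standard.
* **Toxicodynamics (per vHPC, per cycle).** Free APAP is metabolized
  with zonated probability; the metabolite is NAPQI (zonated) or else
  splits equally into G and S. Each NAPQI removal (p = 0.5/cycle)
  decrements the cell's GSH counter; once the counter reaches 0, each
  removal creates `n + 1` damage products (`n` uniform on {3..6}), all
  MitoD or all nonMD. Damage is mitigated with zonated probabilities.
  MitoD strictly above the Necrosis Threshold (4) triggers necrosis with
  a Death Delay drawn uniformly from [2, 6) h; at the due cycle all
  remaining ALT (5 objects per cell at t = 0) is externalized at once.
  Damage strictly above the Leakage Threshold (1) triggers lagged
  single-ALT releases with lags uniform on [0.75, 5) h.
* **Scaling.** Mean ALT-in-Mouse-Body `X_t` maps to plasma concentration
  `Y_t = S * X_t + eps` with `S = 1.72` IU ml^-1 per ALT object, and to
  an individual animal via `y_i,t = delta_i * (S * X_t + eps)`. The
  Individualized Mapping Criterion asks the per-animal skew factors
  `delta_i` to average 1.0 +/- 0.1.

Trials use four named random substreams (disposition, marker, damage,
release), so swapping the release mechanism leaves the APAP disposition
and damage trajectories bit-identical, and the Marker curve is invariant
to every mechanism parameter.

## Worked example

```r
library(hepaltsim)

# medium Dose (50,000 objects = 300 mg/kg), MitoD-Caused mechanism,
# 12 trials on a reduced vLiver of 4 lobules
cfg <- default_vexperiment_config(release_mode = "MITOD",
                                  dose_objects = dose_objects_from_mgkg(300),
                                  n_lobules = 4, master_seed = 20)
res <- run_vexperiment(cfg)
res
#> vExperiment: MITOD mechanism, 50000 Dose objects, 12 trials x 21600 cycles, 4 lobules
#>   Body ALT at end: mean 13384.2 [12656, 13904]
#>   PC Necrosis-Trigger median: 11.4 min;  PC ever-leak-triggered: 60.0%

necrosis_trigger_median_min(res)       # median PC trigger time, minutes
#> [1] 11.38333
100 * leak_triggered_fraction(res, 1800, "PC")  # % PC cells triggered by 30 min
#> [1] 49.79299

# scale the mean Body-ALT curve to plasma ALT (IU/ml)
plasma <- scale_to_plasma(res$body_mean[, "ALT"], scaling_params(S = 1.72))
round(plasma[c(3600, 10800, 21600)], 1)   # 1 h, 3 h, 6 h
#> [1]   392.2 12627.1 23020.9
```

The printed numbers read as follows: roughly half of the pericentral
band experiences a Leakage-Triggered event within 30 minutes of dosing,
the median pericentral necrosis trigger falls in the first quarter hour,
and Body ALT rises sigmoidally toward a plateau set by the number of
damaged cells times 5 ALT objects each, scaled by `S` to IU/ml.

Per-animal skew factors are estimated from a plasma table
(`animal_id,time_h,alt_iu_ml`):

```r
fx <- generate_fixture("synthetic_plasma_table", seed = 1)
dt <- estimate_delta_table(fx$plasma, fx$body_alt)
delta_summary(dt$delta)
#> delta summary (n = 18): mean 1.079  s^2 0.0830  s 0.2882  CV 0.2671
#> Individualized Mapping Criterion (mean 1.0 +/- 0.10): PASS
```

A thin command-line interface over these functions ships in
`inst/cli/hepaltsim.R` with subcommands `structure`, `run`,
`dose-response`, `scale`, `calibrate` and `fixture`.

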