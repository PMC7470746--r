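---
title: "Modelling organosulfur cross-feeding in continuous culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling organosulfur cross-feeding in continuous culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The system and the model

When a lysine auxotroph of budding yeast is starved of lysine — an
"unnatural" limitation its regulatory network never evolved to sense — it
fails to mount the usual slow-growth program and instead releases
organosulfur compounds, mostly glutathione (GSH) and its disulfide
conjugates, into the medium. A second mutant that has lost the ability to
assimilate inorganic sulfate (an organosulfur auxotroph) can live on this
leakage. The two genotypes form a one-way cross-feeding pair whose
coexistence ratio is set by a simple resource balance.

Let `R` and `C` be releaser and consumer cell densities (cells/mL) and `O`
the shared organosulfur pool in GSH equivalents (fmole/mL). Each live
releaser exports `r` fmole/cell/h; each consumer birth costs `c` fmole.
When both genotypes grow at the common rate `g` (in a chemostat, the
dilution rate), the pool obeys

    dO/dt = r R - c g C

and setting it to zero gives the steady-state consumer-to-releaser ratio

    C/R = r / (c g).

`predict_steady_ratio()` evaluates this closed form. With the measured
constants — `r` = 0.02 fmole GSH-equivalent/cell/h, `c` = 2 fmole/cell,
`g` = ln2/8 per hour — it gives 0.115, i.e. roughly one consumer per ten
releasers:

```{r predict}
p <- ecology_params(r = 0.02, c_per_birth = 2, g = log(2) / 8)
predict_steady_ratio(p)
```

## Closing the dynamics

The resource balance alone does not determine dynamics away from the fixed
point, so `simulate_coculture()` closes the system with two explicit model
decisions, both exposed as parameters rather than inferred:

* **Consumer uptake** is Monod: `g_C(O) = gmax_consumer * O / (K_half + O)`.
  Defaults `gmax_consumer = 0.35` per hour and `K_half = 1e5` fmole/mL are
  free closure parameters, chosen to give a consumer that can outgrow the
  shared rate when resource is plentiful and starves smoothly when it is
  not. Consumption is charged per birth, i.e. at rate `c g_C(O) C`, so the
  steady-state balance reads exactly `r R = c g C`.
* **Dilution regime.** Competition experiments ran as serial-dilution batch
  cocultures at roughly constant total density, so the default `"serial"`
  mode applies an effective dilution equal to the density-weighted mean
  growth rate, holding `R + C` constant; `"chemostat"` mode dilutes at a
  fixed rate and `"batch"` mode not at all (useful for mass-budget audits).

One consequence worth stating plainly: in serial mode the resource is
washed out at the effective dilution rate, so the exact fixed point of the
closed system sits slightly below `r/(c g)` — by a factor
`1 - g O*/(r R)` where `O* = K_half g / (gmax_consumer - g)` is the
steady resource level. At the defaults and a total density of 3e6 cells/mL
this is a ~5% shift (0.109 versus 0.115); both round to the observed 0.1.
The test suite checks the simulator against the exact closed-form fixed
point (tight tolerance) and against `r/(c g)` in regimes where the washout
term is negligible.

```{r simulate}
sim <- simulate_coculture(p, init = c(R = 2.7e6, C = 3e5, O = 0),
                          duration = 80, time_unit = "generations")
glance(sim)
```

Integration uses an adaptive solver (lsoda, relative tolerance 1e-8); the
reported `step` only sets the output grid, and halving it changes the final
ratio by far less than 0.1%.

## Measuring the ingredients

**Release rate.** At chemostat steady state `dO/dt = r N - dil O = 0`, so
`estimate_release_rate()` returns `dil * mean(O) / mean(N)` over a
steady-state window (default: the final quarter of the series). On
noise-free synthetic chemostats this inverts the generator exactly.

**Dead-cell attribution.** `dead_release_bound()` multiplies dead-cell
density by the average per-cell content (`per_cell_content()`); a measured
supernatant concentration above that bound cannot be explained by lysis
alone, and `attribute_live_release()` flags it as live release.

**HPLC quantification.** Derivatized glutathione elutes near 7 min, so
`pick_peak()` scans a half-open retention window (default [6.5, 8) min) for
the global maximum that is also a local maximum; a maximum sitting on the
window edge is reported as "no peak". `correct_baseline()` connects the
nearest flanking local minima with a straight line and subtracts it —
exact whenever the true baseline is linear and the peak flanks reach it —
and `integrate_area()` applies the trapezoid rule. Calibration is ordinary
least squares of area against concentration over a 0.03–1 μM working
range; estimates outside it keep their point value but carry a range flag
rather than being censored, because downstream release-rate arithmetic
needs numbers. Tie-breaks are deterministic: equal-height maxima resolve to
the earliest retention time, plateaus to their center sample. No smoothing
is applied by default.

**Bioassays.** The yield assay calibrates tester-strain final turbidity
against known GSH over a user-designated linear range (default 0–2 μM),
with a detection floor at blank mean + 2 blank standard deviations (our
convention; the original blank handling is unstated). One GS-SG yields two
GSH on reduction, so `gssg_to_equivalents()` is exactly ×2. The rate assay
estimates the maximal growth rate and inverts a monotone
concentration-to-rate table by piecewise-linear interpolation — no
parametric form is assumed because none is justified.

**Window statistics.** `max_growth_rate()` fits ln-intensity slopes over
every 4-point sliding window and keeps the steepest, restricted to windows
whose last point is at or below 25% of the series maximum so at least two
doublings of headroom remain; when nothing satisfies the restriction (a
flat series) it falls back to all windows with a warning rather than
erroring, since a flat series has a well-defined zero slope.
`competition_fitness()` takes the steepest 3-point slope of
ln(count ratio) per generation, divided by ln 2 so that a ratio doubling
every generation scores 1; windows containing zero counts are skipped, and
ties go to the earliest window. `frequency_dependence()` pairs each
fitness with the focal fraction at its window start and summarises the
trend by the sign of the Spearman rank correlation — negative under
negative frequency-dependent selection.

## What the generators emulate — and what they do not

The synthetic-data module produces every input the estimators consume,
under the study conditions: lysine-limited chemostats with a 21 μM
reservoir and a yield of 7e6/21 cells·mL⁻¹·μM⁻¹ (so live density
approaches ~7 × 10⁶ cells/mL), releaser kinetics with Monod growth on
lysine (gmax 0.45/h, K 1 μM — plausible values, not measurements),
glutathione-like chromatogram peaks near 7 min on a drifting linear
baseline, yield plates with a saturation ceiling and the ×2 GS-SG
response, competition trajectories sampled from the closed model, and
grow-then-die fluorescence courses. Noise is multiplicative log-normal on
positive-valued measurements, additive Gaussian on detector traces, and
binomial on competition counts (flow-cytometry counting statistics);
magnitudes are free parameters, as the source measurements' noise levels
are not tabulated. With a zero noise spec the competition generator emits
expected counts so that fixed-point and monotonicity properties hold
exactly. Death in the chemostat generator is a constant per-capita
fraction (presets: 10%/h for lysine limitation, 1%/h for glucose
limitation — presets for contrast, not claims), defaulting to zero.

Passing tests on these generators show that the estimators invert the
stated generative models at the stated tolerances. They do not show that
real chromatograms have Gaussian peaks, that real plate noise is
log-normal, or that real cocultures hold total density exactly constant;
matrix effects, retention-time drift across runs, and flow-cytometer
gating error are all outside the emulation.

## Problem sizes and numerical choices

The shipped tests integrate cocultures for 40–100 generations (seconds),
chemostats for 300–400 h of simulated time at 1 h sampling, and
chromatograms at 2–5 ms sampling over 3 min — sizes at which every
closed-form check resolves well below its tolerance. Negative ODE states
beyond a 1e-6 relative tolerance abort with a diagnostic; smaller
excursions are clipped to zero. All schema tables are CSV with
unit-bearing headers (`time_h`, `conc_uM`, ...), read case-insensitively
and tolerantly (extra columns warned and kept), and `run_pipeline()`
writes a JSON provenance sidecar (stage, parameters, seed, version,
checksum) next to every output so any artifact can be regenerated.

## Known limitations

The population closure (Monod constants, dilution regime) is a modelling
decision, not an inference; evolutionary dynamics, lysine dynamics of the
partner strain, and spatial structure are out of scope. The device OD
formula is implemented literally as log10(I/I0) to match the instrument's
logging convention, with a flag for the conventional sign. Whether the
original fitness analysis used per-generation or per-hour axes before the
ln 2 normalization is stated only for generations; the generation axis is
therefore explicit input.
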