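---
title: "Methods: signal chains, tuning statistics and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal chains, tuning statistics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitune)
```

## What this package computes

`calcitune` implements the quantitative chain used to characterize insect
olfactory receptors by calcium imaging: from raw fluorescence recordings to
bleach-corrected response amplitudes, and from amplitude panels to tuning
breadth (lifetime sparseness), dose–response parameters (EC50 and Hill
coefficient), response-spectrum clustering, and the accompanying hypothesis
tests. Because raw recordings of this kind are rarely shared, the package
also ships a synthetic-data generator whose outputs carry planted ground
truth, so the entire chain is validated by *recovery*: simulate with known
amplitudes, rates and EC50s, run the real pipeline, and compare.

## Acquisition model and frame windows

All window constants live in one object, `acq_protocol()`. Recordings are
100 frames at 5 Hz (20 s) with a 1 s odorant stimulus at frames 15–20. Two
presets cover the two recording modes:

* **fly** (single-wavelength GCaMP, transcuticular antennal imaging):
  baseline F0 is the mean over frames 10–14; the response amplitude is the
  mean ΔF/F0 over the 15 frames after stimulation (frames 17–31), relative
  to the F0-defined zero. The phrasing "difference between F0 and the
  average of frames 17–31" is dimensionally consistent only on the ΔF/F0
  scale, so the amplitude is computed on the delta trace; the baseline term
  is retained in the formula for robustness after corrections shift the
  trace.
* **bee** (ratiometric Fura-2, antennal-lobe imaging): the ratio
  R = F340/F380 is formed per pixel or ROI, ΔR/R uses R0 over frames 10–14,
  and the amplitude is the mean over frames 17–19 minus the mean over
  frames 9–11.

Frames are 1-based inclusive everywhere in configuration and reports;
internal arrays are 0-based with a single, tested conversion point.

## Photobleaching correction

Two corrections mirror the two recording modes:

* **Blank-trial subtraction** (fly): the ΔF/F0 trace of a stimulus-free
  recording is subtracted framewise. On simulated data with a shared decay
  this is exact up to the multiplicative interaction between decay and
  transient (< 1 % of the amplitude at the default decay of ~5 % per
  recording).
* **Logarithmic fit** (bee): `a + b·ln(t − t1 + 1)` is fitted by least
  squares to the frames *outside* the window from stimulus onset to 5 s
  after onset (frames 15–40 at 5 Hz) and subtracted everywhere. The
  parametric family of the published correction is not specified beyond
  "logarithmic"; this two-parameter form is the natural choice, fits a pure
  log decay to machine precision (post-correction RMS < 1e-8), and an
  exponential alternative (`model = "exp"`) is provided for sensitivity
  checks. A constant input would make the fit meaningless; it returns the
  mean-subtracted input with a warning.

The 3-point median filter applied before the bee correction is interpreted
as separable width-3 passes along x, then y, then t (not a 3×3×3 cube),
with symmetric edge padding, which for width 3 leaves border samples
unchanged. The implementation is an exact elementwise selection and is
tested against a brute-force per-axis oracle.

## The synthetic generator

`simulate_trace()` builds `baseline × bleach(t) × (1 + a·s(t)) + noise`.
The transient kernel `s(t)` is a difference of exponentials starting at
stimulus onset (defaults: rise 2 frames, decay 12 frames, peaking inside
the response windows); response kinetics are not numerically specified in
the protocols this emulates, so the kernel shape is configuration, not
fact. The kernel is scaled so that the protocol's window-based amplitude
measure of the kernel is exactly 1 — the planted `a` *is* the quantity the
pipeline measures, which makes recovery tests sharp (noiseless, bleach-free
recovery is exact to 1e-12; with the default log bleach the residual
interaction keeps end-to-end error below 2 %).

`simulate_ratiometric_stack()` plants `u = a·s/(2 + a·s)` symmetrically
(+u on F340, −u on F380) so that the pixel ratio change is exactly
`1 + a·s(t)`; both channels share one bleach curve, as for a single dye
excited at two wavelengths. Gaussian noise is the default (`poisson` mode
available for shot-noise robustness checks). What the generator does *not*
emulate: optics/PSF, movement artifacts, mechanistic calcium buffering, or
correlated (non-white) noise — passing recovery tests therefore validates
the arithmetic of the chain, not its robustness to every artifact of real
preparations.

Randomness: a single integer seed expands into counter-based per-replicate
substreams (`seed`, replicate index), so identical configuration and seed
give bit-identical output and growing a panel never reshuffles earlier
replicates.

## Tuning breadth and clustering

Lifetime sparseness is
`S = (1 − (Σ r_i/n)² / (Σ r_i²/n)) / (1 − 1/n)` over a receptor's mean
response spectrum; negative responses are clamped to zero first (the
formula is undefined for them) and the clamp count is reported. S is 0 for
a uniform spectrum, 1 for a single-stimulus specialist, invariant under
positive scaling, and bounded in [0, 1] — all asserted as tests. The
spectrum passed in is the across-animal mean over the panel *including*
controls; clamping is applied to that mean spectrum (per-animal clamping
before averaging would bias small responses upward; the statistic is
defined on the response distribution, which here is the mean spectrum).

Spectra are min–max normalized between the principal-ligand response
(100 %) and the solvent response (0 %) before clustering. Clustering uses
Euclidean distance and average (UPGMA) linkage — the published analysis
names neither, and these are the field's defaults — and both choices are
recorded in the result object and the Newick export.

## Dose–response fitting

The model is the four-parameter Hill curve on log dose,
`y = bottom + (top − bottom)/(1 + (EC50/d)^h)`, the default fit family of
the software this pipeline mirrors. Solvent (0-dose) replicates enter the
loss as observations of the bottom asymptote rather than at an arbitrary
log-dose. Optimization is bounded Levenberg–Marquardt with a deterministic
multi-start (slope 0.5/2/5; EC50 at the half-maximum crossing dose, with a
wider fallback grid), and EC50 is constrained to within one decade of the
tested dose range, outside which the data cannot identify it; fits landing
outside the tested range carry an extrapolation warning. Flat data raise an
explicit flat-curve error.

The default mode fits **per animal** and reports mean ± SEM across animals,
because between-receptor comparisons of EC50/Hill use a Kruskal–Wallis
test, which needs per-animal values; `mode = "pooled"` gives a single fit
with covariance-based SEs. For recovery analyses the dose-series generator
uses measurement noise of 0.05 × the dynamic range, chosen once because it
reproduces the published scale of EC50 SEMs (~20–40 µg at n = 12 around
EC50 ≈ 175 µg); at that scale the median recovered EC50 over 200
simulations is within a few percent of truth and per-animal SEM confidence
intervals cover the truth in ≥ 95 % of runs.

## Hypothesis-testing layer

The three tests used in this kind of study are implemented from their
formulas so every reported statistic is auditable, and each is
cross-checked in the test suite against an independent route (base R's
`friedman.test`/`kruskal.test`, an `aov()` error-stratum fit, and exact
permutation enumerations):

* **Friedman + Dunn** (imaging panels): within-animal ranks with tie
  correction; Dunn z on rank sums, Bonferroni-adjusted by default (the
  documented behavior of the usual commercial implementation), Holm by
  flag. `method = "exact"` enumerates all (k!)^n within-row orderings.
* **Kruskal–Wallis + Dunn** (between-receptor comparisons): tie-corrected
  H; exact mode enumerates all distinct group assignments.
* **RM-ANOVA with Greenhouse–Geisser correction + Dunnett** (SSR and
  dose-response data): epsilon is computed from the double-centered sample
  covariance of conditions, `tr(CSC)²/((k−1)·tr((CSC)²))`, clamped to
  [1/(k−1), 1]; Dunnett's adjusted p uses the multivariate-t distribution
  of the maximum statistic (correlation 1/2, error df (n−1)(k−1)), computed
  numerically to ~1e-5 with a fixed internal seed so results are
  deterministic.

Degenerate designs are resolved explicitly: data identical up to per-animal
offsets give F = 0, p = 1 (null by construction), while zero within-animal
variance alongside real condition differences is an error — no F ratio
exists. Normality screening is left to the user: the tests never
auto-switch based on a normality check, matching an analysis style in which
the test choice is declared per dataset.

Calibration is part of acceptance: at the study's design sizes (12 × 22
Friedman; 16 × 3 RM-ANOVA; 4 × 12 Kruskal–Wallis), empirical type-I error
at α = 0.05 stays within [0.03, 0.07] over 2000 null simulations per test.

## Spike layer

`detect_spikes()` high-passes the trace (2nd-order Butterworth, 300 Hz
default), thresholds at k = 5 robust noise SDs (MAD), and merges crossings
within a 2 ms refractory window; these are conventional defaults, all
configurable, and no equivalence with any specific published detector is
claimed. On an effectively noiseless trace the MAD collapses, and the
threshold falls back to half the peak amplitude. Instantaneous frequency
assigns 1/ISI to each inter-spike interval sampled on a grid, zero outside
spiking epochs. Mean evoked rate is the stimulus-window count rate minus
the baseline-window rate (subtraction on by default). Note that perfect
recall is only defined for trains whose inter-spike intervals exceed the
waveform/refractory width; Poisson trains can violate this physically.

## Problem sizes and determinism

Validation workloads are sized to run quickly at desk scale while keeping
Monte-Carlo error well below the tolerances they check: 200 simulated dose
series for EC50 recovery, 2000 null replicates per test for calibration,
100 seeds for cluster separation, 20 random stacks for the median-filter
oracle. All simulations are seeded; `scripts/acceptance.R` derives every
stream from its `--seed` argument.

## Known limitations

* The logarithmic bleach family and the UPGMA/Euclidean clustering choices
  are conventions where the emulated analyses leave the form unstated; both
  are flagged in results and alternatives are available behind flags.
* The generator's noise is white; correlated noise, movement, and
  segmentation errors are out of scope, so recovery results bound
  arithmetic correctness, not robustness on real preparations.
* Dunn's multiplicity adjustment is Bonferroni (documented commercial
  behavior) — other variants exist and give slightly different adjusted
  p-values.
* The spike layer is single-unit only; no sorting.
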