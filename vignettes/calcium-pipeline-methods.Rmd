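---
title: "Methods: synthetic two-photon sessions and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic two-photon sessions and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

`capipe` implements a complete analysis chain for two-photon calcium
imaging sessions in which a drug is injected after a baseline period and
visual stimuli of varying size are presented: rigid motion correction,
correlation-based soma segmentation, PV+ classification from a red
structural channel, neuropil-corrected ΔF/F extraction, population
activity and drug-epoch statistics restricted to stationary (non-running)
periods, and difference-of-Gaussians (DoG) size-tuning fits with a
surround-suppression index (SSI). Because raw in vivo recordings of this
kind are rarely shareable, the package pairs every stage with a synthetic
session generator that emits the ground truth the stage is supposed to
recover; the test suite and the acceptance script validate the pipeline
against that ground truth, not against in vivo data.

# The synthetic session model

## Spiking

Each cell fires as an inhomogeneous Poisson process binned at the frame
rate. The per-frame rate is

- a spontaneous rate (default 0.03 Hz for population sessions — sparse
  firing, appropriate for cortical neurons recorded in darkness; 0.4 Hz in
  the short rendered fixture so that correlation-based segmentation sees
  enough transients in 150 s),
- plus, during the 2-s drifting phase of each stimulus trial, an evoked
  rate given by the cell's DoG size tuning multiplied by a wrapped-Gaussian
  orientation factor (width default 30°),
- multiplied by the treatment's `drug_gain` from the injection frame on
  (a step change; the generator makes no attempt to model the gradual
  onset of a systemic drug),
- optionally multiplied by a shared excitability modulation common to all
  cells (below).

Poisson spiking is the simplest driver with controllable means; its
Fano factor of 1 sets the statistical precision attainable by any
downstream estimate, which is why the validation conditions state session
counts explicitly.

Default drug gains are saline 1.0, MK-801 0.65, MK-801 + ACC muscimol
0.86, and 3.0 for the top-down axon condition; these mirror the effect
magnitudes the pipeline is designed to resolve and are configuration
values, not measurements.

## Shared modulation

Cortical populations show correlated slow excitability fluctuations, and
the excitatory/inhibitory correlation analysis is meaningless without
them. The generator therefore multiplies all cells' rates by a common
band-limited process: Gaussian noise smoothed with a 5-s window, with
components slower than 30 s removed, scaled to SD 0.3 around 1 and clamped
at 0. The band limit is deliberate: slow shared drift is already
represented by the neuropil field, and within a single session an
unremoved slow component would be statistically indistinguishable from a
treatment effect, confounding the drug-epoch estimates the generator is
supposed to calibrate.

## Fluorescence and rendering

Spikes are convolved with a difference-of-exponentials kernel (0.2 s
rise, 1.8 s decay — GCaMP6s-like, configurable), normalized to unit peak,
scaled by 20 a.u. per spike and added to a resting fluorescence of 100
a.u. No indicator-binding nonlinearity is modeled: fluorescence is affine
in spike counts, which is what makes ground-truth comparisons exact.

Rendered sessions place somata as annular ("donut") intensity profiles —
nuclear exclusion, so segmentation faces realistic geometry — whose
mask-mean equals the cell trace by construction. Background pixels carry
a shared neuropil field: a smooth spatial map (Gaussian-blurred noise,
relative SD 0.25) times a slow positive temporal trace (mean 60 a.u.,
smoothed noise plus a slow sinusoidal drift). Soma pixels receive the
cell signal **plus 0.7 × the local neuropil** — the contamination the
0.7-weighted subtraction is designed to remove — plus i.i.d. Gaussian
noise (default SD 2 a.u.). The red channel fills PV+ somata at intensity
1.0 and others at 0.15 (threshold 0.5), with thin 1-px "processes" that
the erosion/dilation step must remove.

Locomotion alternates stationary and running bouts with exponential
durations (default: 0.02 bouts/s, 15% of time running, ~8 cm/s); the
running threshold used in analysis (1 cm/s with 1-s padding) is a
pipeline parameter, since no numeric definition of "non-running" is
standard.

## What the generator does not emulate

No optical point-spread function, no sub-pixel or non-rigid motion, no
indicator saturation or bleaching, no spatially heterogeneous neuropil
contamination weights, and no drug effects on tuning shape (the drug is a
pure rate gain, so a generator session cannot reproduce a treatment
-induced change in SSI; the pipeline measures such changes but the
synthetic calibration cannot certify them). Passing tests therefore
demonstrate correctness of the computations under these idealizations,
not robustness to every property of real data.

# Pipeline stages and numerical choices

**Registration.** Integer-pixel rigid shifts only, estimated per frame by
the cross-correlation peak (computed in the Fourier domain over circular
shifts, validated in the tests against an exhaustive spatial-domain
search). Pre-injection data are registered to the mean image of the
post-injection epoch. A 20-µm border is cropped (`ceil(border/pixel)`
pixels per side) so every retained pixel exists in all frames. Frames
whose normalized correlation peak falls below 0.2 are flagged
low-confidence. Sub-pixel refinement is deliberately out of scope.

**Segmentation.** Somata are grown greedily from seed pixels taken in
decreasing temporal-variance order (above the 0.9 variance quantile),
adding 4-connected neighbors whose Pearson correlation with the current
ROI mean exceeds 0.4; regions outside 30–400 px are discarded.
Correlation and variance are computed on high-pass-filtered pixel traces
(each pixel minus its own 10-s moving average): without this, the slow
shared neuropil correlates neighboring background pixels above any usable
threshold and region growth leaks. 4-connectivity was chosen over
8-connectivity to limit leakage between adjacent cells. The manual
curation of the original workflow is replaced by the area filter plus a
machine-readable quality score (mean within-ROI pixel correlation).
Bouton detection is an automated stand-in for manual annotation:
percentile thresholding of the mean image plus connected components
within area bounds, flagged `automated` in the metadata.

**PV classification.** The red mean image is thresholded, eroded and then
dilated with disc structuring elements (radius 2 px) to remove thin
labeled processes; an ROI is PV+ when ≥ 50% of its pixels fall in the
cleaned mask. Raising the threshold can only remove PV labels
(monotonicity, tested).

**Trace extraction.** ROI traces are unweighted pixel means. The
neuropil estimate is the mean over a 30-µm annulus around the ROI
excluding all ROI pixels, subtracted with weight 0.7. Cells not strictly
more than 5% brighter than their annulus (baseline-epoch means) are
excluded; the boundary case (exactly 5%) excludes. F0 is the **median**
of the corrected trace over the baseline epoch; ΔF/F = (F − F0)/F0.
Corrected fluorescence is not clipped at zero (clipping would bias
ΔF/F); excursions below −1 are counted and reported. No detrending is
applied before or after the subtraction.

The F0-median convention is unbiased only when the cell is silent in most
baseline frames; that is exactly the sparse-firing regime the population
generator defaults to. At higher spontaneous rates the median sits above
the true resting fluorescence and fractional-change estimates inflate —
a property of the convention itself, which the synthetic sessions make
visible.

**Population and drug statistics.** Population traces are unweighted ROI
means smoothed with a 2.5-minute centered boxcar, truncated at the
edges (the kernel shape is a choice; only the window length is given by
convention). Fractional change compares the stationary-frame mean over
the 20–30-minute post-injection window with the stationary-frame mean
over the baseline epoch. E/I correlation is the Pearson r of the two
unsmoothed population means; E/I coupling smooths both traces with a 5-s
boxcar, normalizes each to its baseline mean, and divides E by I
pointwise — the normalization makes the ratio exactly invariant to any
gain applied to both populations. The coupling is computed on
baseline-normalized fluorescence (1 + ΔF/F) rather than raw ΔF/F, whose
near-zero baseline mean would make the ratio numerically meaningless.

**Size tuning.** The response amplitude of a trial is the maximum ΔF/F
during the 2-s drifting phase; trials with any running frame are flagged
and excluded from averages. The DoG model is evaluated in closed form,
R(s) = Rb + Ke·(a√π/2)·erf(s/a) − Ki·(b√π/2)·erf(s/b), verified against
adaptive quadrature of the integral form to 10⁻⁶ relative error. Fits
minimize the sum of squared residuals with box bounds, constraint a ≤ b
(center narrower than surround — resolving the sign/width ambiguity of
the difference form), and 20 multi-start runs over log-spaced space
constants with seeded jitter, because the SSE surface is multimodal.
The preferred size is located on a 0.1° grid within the tested range;
r_max is the fitted response at the largest tested size;
SSI = (r_pref − r_max)/r_pref, undefined (flagged, not coerced) when
r_pref ≤ 0. Both population-level and per-neuron fits are available.

Responsiveness for per-neuron analyses defaults to a pre-epoch
preferred-size response above 2 baseline-noise SDs. A caution the
synthetic data make explicit: selecting each neuron's preferred size on a
noisy pre-epoch curve biases the pre response upward, so per-neuron
"fractional change at preferred stimulus" is systematically negative even
under saline (regression to the mean). The population-curve statistics do
not suffer from this selection.

**Group statistics.** Kruskal–Wallis (with Tukey–Kramer-corrected
pairwise comparisons on mean ranks), one-way and two-way ANOVA (with
`TukeyHSD`) are delegated to base R; the module's contribution is the
wiring: ROI-level samples with session counts reported alongside, flags
for degenerate inputs, and a deterministic JSON/CSV report (no
timestamps, so identical inputs give byte-identical files). A
calibration routine simulates null session triplets (Poisson counts,
equal rates) and checks the 5% level empirically.

# Validation problem sizes

The standard rendered fixture is 20 somata (5 PV+) in a 140×140 µm field,
150 s at 10 Hz, pixel noise SD 2. Population sessions are 200 cells with
the full 6-min baseline and 45-min post epochs at 10 Hz, trace-level
(rendering pixels for 200 cells adds nothing to trace-level statistics
and the pixel path is fully exercised by the rendered fixture).
Drug-gain recovery is validated on 4 sessions per condition: a single
session's fractional-change estimate carries irreducible Poisson noise of
roughly ±0.07 at a gain of 3 under these conditions, and pooling a few
sessions is also how the corresponding in vivo analyses are reported.
DoG identifiability uses 200 noiseless curves with SSI in [0, 0.8] (max
recovery error ≤ 0.02) and 10%-noise curves with 10 trials per size
(median error ≤ 0.1). Statistical calibration uses 1000 simulated
triplets.

# Known limitations

- Integer-pixel registration cannot represent sub-pixel motion; on real
  data a sub-pixel method would precede this pipeline.
- The correlation-growing segmenter assumes activity-driven contrast;
  silent cells are invisible to it by design.
- The E/I correlation magnitude in synthetic sessions depends strongly on
  the shared-modulation amplitude and the sparse firing regime; it is a
  generator setting, not a prediction.
- Animal-level clustering is not modeled in the group statistics
  (ROI-level tests with session counts reported); a mixed-effects
  extension would be the natural next step.
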