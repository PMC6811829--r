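# capipe — two-photon calcium imaging analysis with synthetic ground truth

`capipe` is an R package plus analysis workflow for a common class of
two-photon calcium imaging experiments: record a population of cortical
neurons (or axonal boutons) through a baseline period, inject a drug
(e.g. the NMDA-receptor antagonist MK-801, with or without concurrent
muscimol inactivation of a projection source), continue recording for
tens of minutes under visual stimulation with drifting gratings of
varying size, and ask how spontaneous activity, evoked responses and
surround suppression change.

It is written for imaging labs and methods developers who need the full
chain — movie in, statistics out — in tested, reusable form:

1. **Registration** — rigid integer-pixel motion correction by
   cross-correlation, pre-injection epoch registered to the
   post-injection mean, 20-µm border crop.
2. **Segmentation** — somata by greedy grouping of pixels with
   correlated time courses; boutons by thresholding the mean image; PV+
   classification from an eroded-then-dilated red-channel mask.
3. **Trace extraction** — ΔF/F with neuropil correction
   (soma − 0.7 × annulus), a strict >5% soma-brightness inclusion
   filter, and F0 = median of the baseline-period trace.
4. **Population dynamics** — 2.5-minute-smoothed population traces,
   locomotion masking, fractional change of activity at 20–30 min post
   injection, excitatory/inhibitory correlation and coupling.
5. **Size tuning** — trial amplitudes (max ΔF/F in the 2-s drift phase,
   moving trials excluded), difference-of-Gaussians fits, surround
   suppression index.
6. **Group statistics** — Kruskal–Wallis / ANOVA with Tukey–Kramer
   pairwise correction, and deterministic JSON/CSV reports.

Because raw recordings of this kind are rarely deposited, the package
includes a first-class **synthetic session generator**: donut-shaped
somata on a diffuse neuropil background with a known contamination
weight, GCaMP6s-like transient kinetics driven by stimulus-tuned Poisson
spiking, locomotion bouts, and a step gain change at the injection frame.
Every stage of the pipeline is validated against this ground truth.

## The model at the core

Size tuning is fit with a difference-of-Gaussians (DoG) model: the
response to a grating of diameter *s* is

    R(s) = Rb + Ke ∫₋ₛ/₂^ₛ/₂ e^−(2y/a)² dy − Ki ∫₋ₛ/₂^ₛ/₂ e^−(2y/b)² dy
         = Rb + Ke (a√π/2) erf(s/a) − Ki (b√π/2) erf(s/b)

with excitatory/inhibitory gains Ke, Ki and space constants a ≤ b. The
surround suppression index is

    SSI = (R_pref − R_max) / R_pref

where R_pref is the fitted response at the preferred size and R_max the
fitted response at the largest tested size. Fits are multi-start bounded
least squares (the SSE surface is multimodal) and deterministic given a
seed.

## Worked example

```r
library(capipe)

# a 45-minute MK-801 session: 200 cells, trace-level, seeded
cfg <- session_config(treatment = "mk801", rng_seed = 1L)
ses <- simulate_session(cfg, n_cells = 200, n_pv = 40, stimuli = FALSE,
                        render = FALSE)
ses
#> Synthetic session: 200 cells (40 PV), 30600 frames @ 10 Hz, treatment mk801 (gain 0.65) [trace-level]

res <- analyze_population_session(ses)
res$population_fractional_change
#> -0.344
```

The generator applied a rate gain of 0.65 at the injection frame, so the
expected fractional change of spontaneous activity at 20–30 minutes post
injection is −0.35; the pipeline (ΔF/F with baseline-median F0,
stationary frames only) recovers −0.344 on this session.

```r
# size tuning: fit a DoG to a curve and read off the suppression index
sizes <- seq(10, 60, 10)
y <- dog_response(dog_params(0, 1, 0.245, 15, 45), sizes)
round(y, 3)
#> [1] 6.287 7.909 6.839 5.560 4.657 4.103
fit_dog(sizes, y, seed = 1)
#> DoG fit: Rb=-0.000343 Ke=1 Ki=0.245 a=15 b=45 | s_pref=18.9 deg, SSI=0.482 (SSE=4.16e-10)
```

The response peaks near 19° and falls by ~48% at 60°: SSI 0.482.

The full study is scripted under `analysis/` (run in order,
`01_simulate_sessions.R` … `06_group_stats.R`); each script prints what
it found and writes tables under `results/`.

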