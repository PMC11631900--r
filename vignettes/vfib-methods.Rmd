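---
title: "Methods: a desk-scale pipeline for ventricular fibrillation under acute ischaemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale pipeline for ventricular fibrillation under acute ischaemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices behind **vfib**: a desk-scale
(single CPU, minutes-not-days) simulation and analysis pipeline for
ventricular fibrillation (VF) under graded acute myocardial ischaemia, from
single-cell electrophysiology to tissue-level fibrillation and clinical ECG
markers.

## 1. The reduced ionic model

Human ventricular models with full ionic detail are too slow for 2D
fibrillation runs on one CPU, so `vfib` ships a single reduced
Hodgkin–Huxley-style model (12 state variables) whose parameters are
calibrated to human anchors rather than ported equation-by-equation:

* **Fast sodium current** with `m`, `h`, `j` gates. Recovery from
  inactivation below −40 mV is slowed by a fixed factor relative to the raw
  rate functions. This separates two roles of the `h`/`j` kinetics: slow
  *diastolic* recovery gives post-repolarisation refractoriness and a steep
  short-DI restitution foot, while the fast *suprathreshold* branch keeps the
  upstroke sensitive to inactivation-time-constant scaling, so that the
  VF-variant deltas (see below) genuinely slow conduction.
* **Late sodium current** with ORd-style activation/inactivation and a
  configurable inactivation time constant.
* **Slow inward (L-type-calcium-like) current** driving the plateau and a
  minimal intracellular calcium balance.
* **Repolarising currents**: delayed rectifier (with the restitution "clock"
  in its slow deactivation), inward rectifier, plateau and background
  potassium currents, and a transient outward current shaping the
  spike-and-dome morphology.
* **ATP-sensitive potassium current** `I_K(ATP)` with an activation fraction
  and the conventional `(Ko/5.4)^0.24` conductance scaling; this is the
  hypoxia arm of the ischaemia configuration.

Calibration anchors (published human data):
APD90 at 2 Hz pacing within the human experimental band, transmural APD
ordering (epi < endo < mid) via delayed-rectifier/slow-inward factors, an
apicobasal repolarisation gradient of about 11 ms, conduction velocity
65 cm/s longitudinal and 50 cm/s transverse after conductivity calibration,
and the restitution-slope targets of the VF-optimised variant.

### Ischaemia configuration

`ischaemia_config()` bundles hyperkalaemia (extracellular potassium),
`I_K(ATP)` activation, and acidosis scales on the fast sodium and slow inward
conductances. The presets are `healthy` (Ko 5.4 mM), `mild` (Ko 7 mM, katp
0.001) and `moderate` (Ko 8 mM, katp 0.003, 15% current block). The moderate
preset is gentler than the severest values used in large 3D simulations
(Ko 9 mM, 25% block)
because the reduced model loses tissue-level propagation entirely there; the
chosen values preserve the qualitative behaviour that matters for the
pipeline (APD ordering moderate < mild < healthy for every cell type, and VF
extinction under moderate remote ischaemia). The absolute moderate APD
(~40–50 ms) is shorter than the experimental band — a documented limitation
of the reduced model.

### The VF-optimised variant

`vf_variant_delta()` applies the VF-optimising parameter deltas: inactivation
time constants of the fast sodium current halved (tau_h, tau_j × 0.50), late
sodium inactivation reduced by 34% (tau_hL × 0.66), and both conductances
increased by 39%. On the calibrated baseline this reproduces:

* maximal S1S2 APD90 restitution slope ≈ 0.6 for diastolic intervals above
  280 ms and ≈ 3.7 below (the calibration targets, within ±20%);
* a restitution curve steeper than the baseline's;
* a larger dynamic-restitution alternans amplitude than the baseline;
* ≈ 5% conduction-velocity slowing at fixed conductivity.

```{r}
library(vfib)
variant <- make_cell_model(delta = vf_variant_delta())
curve <- s1s2_restitution(variant)
max_restitution_slope(curve, di_split = 280)
```

## 2. Protocols and the population-of-models cascade

`s1s2_restitution()` paces 10 S1 beats at 600 ms and probes premature S2
beats from 200–600 ms in 10 ms steps, refining with 2 ms steps around the
shortest captured interval; a beat "captures" when its peak exceeds 0 mV
within 50 ms of the stimulus. `dynamic_restitution()` paces decreasing cycle
lengths and reports the maximal beat-to-beat APD difference as the alternans
amplitude. `ramp_pacing_schedule()` is the VF-induction ramp (2 × 350,
3 × 325, 5 × 300, 5 × 275, 6 × 250 ms; about 6 s).

The population layer follows the standard two-stage calibration cascade:
`lhs_population()` draws Latin-hypercube scalings of the sodium, calcium and
delayed-rectifier currents and their inactivation kinetics;
`calibrate_population()` filters on healthy then on ischaemic biomarker
ranges; `select_vf_candidates()` ranks by restitution steepness and picks the
largest-alternans member, excluding members with repolarisation
abnormalities (`detect_repolarisation_abnormality()`). Population counts of
the scale reported for such cascades (1000 → 475 → 275) depend on external
experimental ranges that are not available offline, so they are documented
here rather than asserted by tests.

## 3. Tissue: monodomain sheet with regional ischaemia

`build_tissue()` lays out a 2D sheet with an ischaemic core disc (transmural)
or half-disc (subendocardial) at a stereotyped location (anteroseptal,
lateral, inferior, or control), a lateral border zone where all ischaemic
parameters grade linearly with Euclidean distance over the border width, and
transmural cell-type bands (50% endocardial / 30% mid-myocardial / 20%
epicardial). The remote myocardium follows a `severity_protocol()`: I stays
healthy, II switches healthy → mild, III mild → moderate, with parameters
switching exactly at the protocol times.

The solver is operator-split and explicit: Rush–Larsen gating updates,
forward-Euler reaction, and flux-form anisotropic finite-difference diffusion
with no-flux boundaries (the flux form conserves the spatial mean to
round-off, which the tests assert at 1e-10). Gate rates are tabulated on a
0.05 mV grid. The default step `dt = 0.02–0.03 ms` must satisfy the explicit
stability bound `dt <= dx^2 / (4 D)`, which `run_monodomain()` enforces.

Conductivity is not a free parameter: `calibrate_conductivity()` fixes the
longitudinal diffusivity so a planar wave in the healthy baseline strand
travels at 65 cm/s (the package default is this calibrated value), the
transverse-to-longitudinal ratio is `(50/65)^2`, and
`conductivity_scale_for_cv_ratio()` computes the reduced-conductivity factor
for the fibrillation substrate (baseline CV ratio 0.8). With the variant
deltas on top, total CV reduction is ≈ 24% vs the healthy baseline — the
"25% total reduction" composition (0.95 × 0.8).

`pseudo_ecg()` computes infinite-medium unipolar potentials from the spatial
gradient of membrane potential (−∇Vm·∇(1/r) integral) at five named bipolar
pairs (`electrode_set()`), mirroring defibrillation-pad-like configurations.

## 4. Phase singularities

`detect_ps()` implements the standard dual-isosurface criterion reduced to
2D: phase singularities are intersections of the `Vm = −40 mV` isoline with
the `dVm/dt = −2 mV/ms` isoline, with chirality from the sign of the
Jacobian determinant of the two fields. `phase_winding_ps()` is the
independent oracle: plaquettes of the Hilbert-phase field with ±2π winding.
On very coarse grids (a wavelet spanning < 10 cells) the isoline criterion
can register several crossings along one conduction-block line; since the
desk-scale sheet is only inducible at such resolutions, exact-count agreement
between the two methods is asserted on resolved phantom spirals, and on PDE
re-entry the cross-check is rotor presence/absence plus the oracle's exact
single-rotor count. `ps_timeseries()` samples the movie frame nearest each
analysis-window midpoint.

## 5. ECG markers and stratification

`preprocess()` resamples each analysis window to 250 Hz (polyphase,
anti-aliased), cuts 512 samples (2.048 s), removes the mean and applies a
Tukey(0.2) taper. `amsa()` is the sum over 2–48 Hz spectral bins of
amplitude × frequency (one-sided 2|X|/N spectrum), `dominant_frequency()`
the argmax bin, `median_slope()` the median absolute first difference times
the sampling rate. `window_markers()` assembles the per-lead, per-window
marker table with PS counts at window midpoints; `window_labels()` attaches
the remote-severity label at the window midpoint and flags the first
post-induction window (onset), which `stratify_by_severity()` excludes by
default. `threshold_flags()` applies the clinical
favourable-prognosis thresholds (AMSA 15.5 mV Hz, median slope 2.6 mV/s).

## 6. Synthetic data

The analysis layers are testable without any PDE run: `surrogate_vf_ecg()`
generates seeded sums of sinusoids with controlled band content (and
severity-styled presets matching the DF/amplitude regimes by severity), and
`phantom_spiral_movie()` builds membrane-potential movies from Archimedean
spiral phase fields with exactly known singularity positions and
chiralities. `scenario_grid()` enumerates the 21 scenario descriptors
(control + 3 locations × 2 extents, × 3 protocols).

## 7. Desk-scale limitations

* 2D sheets replace the 3D biventricular–torso anatomy: absolute PS counts
  and AMSA values are not comparable to 3D biventricular simulations, only
  directions and orderings are asserted.
* The mild-remote VF wavelength exceeds a 24 mm sheet, so desk-scale
  re-entry is transient (several rotations anchored at the ischaemic core)
  rather than sustained multi-second VF; escalation to
  moderate remote ischaemia terminates it, the expected direction.
* The reduced moderate-ischaemia action potential is shorter than the
  experimental band (see section 1).
* A control (non-ischaemic) sheet is not inducible by cross-field
  stimulation at any tested coupling: without ischaemic dispersion of
  refractoriness there is no vulnerable window.
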