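---
title: "Simulating early ischemic ECGs and ST-deviation detection with ischsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating early ischemic ECGs and ST-deviation detection with ischsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Within the first ten minutes of a coronary occlusion, ischemic myocardium
depolarizes at rest, loses action-potential amplitude, repolarizes
earlier, and conducts more slowly. These changes drive injury currents
that surface in the ECG mainly as ST-segment shifts — but many early
events are "electrically silent" in the standard 12-lead ECG. `ischsim`
provides a self-contained, fully synthetic simulation study of this
regime: it generates parametric biventricular anatomies inside
cylindrical torsos, simulates single paced beats with hemispherical
subendocardial-to-transmural ischemic regions of graded severity,
derives standard and extended body-surface lead systems, extracts two
ST-deviation features, and computes in-silico detection-rate statistics
across decision thresholds, lead systems and ischemia characteristics.

Everything is generated by code: there is no patient data, no imaging,
and no fitted model. The value of the package is the *logic* of the
study — which lead systems and features can, in principle, see which
kinds of early ischemia — not absolute microvolt predictions for any
real torso.

## The pipeline and its assumptions

**Anatomy** (`build_ventricles()`, `assign_aha_segments()`). The left
ventricle is a truncated half-ellipsoid shell (endocardial short
semi-axis, apex-base length, and base/apex wall thicknesses per
subject), the right ventricle a thinner crescent obtained by carving the
LV out of a laterally shifted shell. This is the simplest geometry that
supports the three structural features the study needs: a 17-segment AHA
parcellation, a transmural depth coordinate, and subject-to-subject
wall-thickness variation. Transmural depth is
`d_endo / (d_endo + d_epi)` from the euclidean distances to the two
surfaces, 0 on the endocardium and 1 on the epicardium. For the septal
wall the "far" surface is the RV-facing side, so septal setups can
reach transmurality. Voxels are cubic; 1 mm is the geometry default and
2 mm the fast mode used for full sweeps (the features of interest are
mm-scale, and every acceptance property is checked at 2 mm).

Three default subjects ("VM-like", "K-like", "D-like") differ in wall
thickness (12/10/9 mm at the base), ventricle size, torso size, and
heart position/orientation, so inter-subject feature spread is nonzero.
The thick-walled VM-like subject is the one whose ischemia radius series
extends to 30 mm.

**Ischemia geometry** (`place_ischemia()`). A setup is a sphere centered
on the endocardial surface at the centroid of one AHA segment —
effectively a hemisphere inside the wall. The zone factor (ZF) is 1 in
the central ischemic zone (CIZ), 0 outside the total radius, and ramps
*linearly* across the border zone (BZ); linearity is the minimal
assumption for a graded transition and is the one configurable choice of
the severity model. A setup is *transmural* when a CIZ voxel touches
(is 26-adjacent to) the epicardial surface; BZ contact alone does not
make the whole wall ischemic and therefore does not count. The default
grid — 17 segments × 3 BZ radii (2.8/4.8/9.6 mm) × total radii
5–25 mm for two subjects and 10–30 mm for the thick-walled one — yields
765 setups.

**Electrophysiology** (`ap_params()`, `ischemia_endpoints()`,
`tmv_course()`, `params_at()`). Each voxel's transmembrane voltage
follows a phenomenological template parameterized by resting voltage,
amplitude, APD90 and conduction velocity: rest, a 2 ms linear upstroke,
a plateau, and a half-cosine repolarization anchored exactly at the
90%-repolarization definition. Parameters interpolate linearly in ZF
between a healthy endpoint and a fully ischemic endpoint per transmural
layer (endo/mid/epi at depth thirds). Defaults are representative
textbook values for about ten minutes after onset: healthy rest −85 mV,
amplitude 125 mV, APD90 320/340/300 ms (endo/mid/epi, M-cell-like
mid-wall maximum, epicardium shortest — producing concordant T waves),
CV 0.6 m/s; ischemic rest −70 mV, amplitude 95 mV, APD90 −25%, CV −40%.
They are configuration, not fitted values, and BZ voxels scale both the
ischemic shift and the transmural heterogeneity multiplicatively.

The plateau occupies 25% of APD90 before repolarization begins
(`plateau_frac = 0.25`). This default was chosen so the healthy ST
segment sits in the near-isoelectric clinical regime: a perfectly flat
plateau makes the healthy heart *exactly* silent between QRS and T
(degenerate — every physiological reference value collapses to zero),
while a much earlier repolarization onset pushes the T-wave upstroke
into the ST measurement window and biases it positive.

**Excitation spread** (`compute_activation()`). The event-driven
cellular automaton is realized as a multi-source first-arrival
(Dijkstra) problem on the 26-neighbour voxel graph with edge travel
time = euclidean length / harmonic mean of the endpoint velocities
(harmonic averaging composes travel times consistently across an
interface). This is equivalent to the automaton at the 0.1 ms clock the
results are rounded to, and is testable against an independent
brute-force shortest-path oracle. Conduction is isotropic (fiber
architecture is out of scope); anisotropy can enter through the
per-voxel CV field. About ten endocardial early-activation sites with
delays of 10–30 ms emulate the His–Purkinje system; the delays start at
10 ms so that the first five saved frames (0–8 ms) are strictly
diastolic and can serve as the baseline. With the default sites the
healthy ventricles finish activating in under 120 ms, i.e. within a
non-pathological QRS duration.

**Forward model** (`lead_field()`, `compute_bspm()`). Every voxel
contributes an equivalent current dipole proportional to the negative
spatial TMV gradient (central differences, one-sided at surfaces), and
electrode potentials are the infinite-homogeneous-medium dipole sum
`(r_e − r_v) · p / (4πσ|r_e − r_v|³)`. This preserves the source physics
that generates ST shifts; torso inhomogeneities mainly rescale
amplitudes. Because absolute amplitudes in an infinite medium are not
directly comparable to thresholds in microvolts, each subject is
calibrated once so the physiological 12-lead peak equals 1.5 mV — a
typical QRS amplitude — and the same factor is reused for all of that
subject's ischemic beats. Baselines are removed per lead as the mean of
the first five (diastolic) frames, which is what converts diastolic
injury currents into the clinically familiar ST shift.

**Lead systems** (`place_electrodes()`, `extract_scenario()`). The
body-surface map is a Fibonacci lattice on the lateral torso cylinder
(600 electrodes by default, ≈4 cm mean spacing on the default torso),
plus deterministically placed standard electrodes; V3R–V6R mirror V3–V6
across the sagittal plane. All unipolar leads reference the Wilson
central terminal. Scenarios: `3-channel` (I, II, III, aVR, aVL, aVF),
`12-lead`, `12+R` (plus V3R–V6R), `12+1` (plus one lattice unipolar),
and `BSPM`. One deliberate convention: the `BSPM` scenario contains all
unipolar leads *and* the derived limb/augmented/precordial leads. A
bipolar limb lead can exceed every unipolar in magnitude, so a
unipolars-only BSPM would not be guaranteed to dominate the 12-lead
ECG; including the derived leads (which a clinical BSPM acquisition
retains anyway — its electrodes include the limb electrodes) makes the
lead-system ordering BSPM ⊇ 12+1/12+R ⊇ 12-lead ⊇ 3-channel an exact
superset relation, and detection-rate monotonicity across lead systems
an exact consequence of the features' max/min-max structure.

**Features** (`stsd()`, `k_point()`, `kpd()`, `per_lead_feature()`).
STSD is the maximum over leads of |mean of the 25 samples at 110, 112,
…, 158 ms|. The K point is the time in [40, 320] ms (R peak to T peak)
at which the across-lead envelope of absolute values is minimal
(earliest frame on ties — the tie-break is a deterministic convention),
and the KPD is the envelope value there. The elevation-only variant
clips negative samples to zero *before* the envelope and recomputes its
own K point under clipping; this is one of several reasonable
formalizations of "pure elevation" and is fixed as the package's
convention. Alternating deviation (elevation early in the ST segment,
depression later) cancels in the STSD mean but cannot push the envelope
to zero, which is exactly what the packaged `alternating_st.csv`
fixture demonstrates (STSD exactly 0, KPD 48 µV).

**Study engine** (`run_study()`, `detection_rate()`, `averaged_rate()`,
`subgroup_report()`, `optimize_additional_electrode()`,
`segment_threshold_80()`, `physiological_threshold()`). A detection at
threshold τ is `feature ≥ τ` (inclusive). Threshold-free summaries
average the rate over 54 equidistant thresholds on 24–240 µV for STSD
and 36 on 9–150 µV for KPD. Setups are pooled across subjects before
averaging; per-subject breakdowns are available via
`subgroup_report(by = "subject")`. The 80%-coverage threshold per AHA
segment is the largest τ with rate ≥ 0.8, which under the inclusive
rule is the lower 20th percentile of the observed values — the search
runs over observed values because the rate is a step function. The 10th
electrode is optimized over all lattice candidates against the
KPD-grid-averaged rate (matching how the extended-lead results are
summarized; single-threshold objectives are a trivial variant), with
ties broken to the lowest electrode index, one fixed position per
subject (`individual`) or one shared lattice position (`common`).
Per-candidate 12+1 features and per-lead values at the shared 12-lead K
point are retained during the run, so optimization and per-lead
sensitivity maps need no re-simulation. The `12+1` rows of the study
table use each subject's individually optimal electrode.

## What the generator emulates — and what it does not

The synthetic anatomies reproduce the *statistical structure* the study
needs: wall thickness differences between subjects (so identical radii
are transmural in one subject and subendocardial in another), varying
heart position/orientation relative to the electrodes (so optimal
electrode positions are subject-specific), and quasi-uniform torso
coverage. They do not emulate real torso geometry, tissue
inhomogeneities (lungs, blood, fat), fiber-driven anisotropy, atrial
activity (no P wave), beat-to-beat variability, or measurement noise.
Consequently, passing tests demonstrate internal consistency and the
qualitative electrophysiology (depression for subendocardial setups,
elevation for transmural ones, rates increasing with ischemia size,
ordering of lead systems and features) — not clinical sensitivity
values. Absolute detection rates from the synthetic population are
expected to differ from values obtained on segmented human anatomies,
and specificity cannot be assessed at all because no non-ischemic
confounders are modeled.

## Numerical choices

* Voxel indexing is 0-based with `index = floor(coord / voxel_size)`;
  hearts are built in a local frame (apex toward −z) and placed by a
  rigid transform, so AHA labels are placement-invariant by
  construction.
* Distances to surfaces are exact nearest-surface-voxel distances
  (compiled brute force); per-chamber connectivity is enforced by
  keeping the largest 26-connected component.
* The activation clock is 0.1 ms; frames are saved every 2 ms over a
  500 ms beat (251 frames).
* Degenerate inputs error early and by name: negative lengths, wall
  thickness ≥ short axis, epicardium not enclosing the endocardium,
  off-surface ischemia centers, empty segments, unknown scenarios or
  config keys, records not covering the feature windows.
* The default study resolution in `study_config()` is 2 mm (the full
  765-setup sweep at 1 mm is possible but is a long, memory-hungry run;
  the anatomical default of `build_ventricles()` remains 1 mm).
* Problem sizes used by the test-suite and the acceptance script (the
  package's own fast-sweep choice): 2 mm voxels, one subject,
  17 segments × 2 radii × 1 BZ = 34 setups, 200 lattice electrodes; the
  oracle checks use 100 random records and 20 random ≤12³ grids.

## Known limitations

* The infinite-medium dipole sum ignores the torso boundary; amplitudes
  are made meaningful only through the per-subject 1.5 mV calibration.
* The ZF-to-parameter mapping is linear by assumption; a cell-model
  derived mapping could be substituted through
  `ischemia_endpoints()`/`params_at()` without touching the rest.
* One beat, no refractoriness, no reentry, no rate dependence.
* The K-point-elevation convention (clip before envelope, recompute the
  K point) is one of several defensible readings of "pure elevation".
* The per-subject radius series reproduce the published total of 765
  setups, but the exact per-subject radius lists are a design choice of
  this package.
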