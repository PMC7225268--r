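---
title: "Methods: recording-quality metrics and micromotion strain modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recording-quality metrics and micromotion strain modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imetk)
```

`imetk` implements the two quantitative workhorses of chronic intracortical
microelectrode (IME) benchmarking in rodents: a recording-quality pipeline
that turns raw multi-channel extracellular voltage into five comparable
session metrics plus a nested general-linear-model group comparison, and a
three-dimensional linear-elastic finite-element model of the tissue strain a
stiff silicon shank induces when micromotion displaces it tangentially
relative to the brain. Both are exercised entirely on synthetic data with
known ground truth, so every stage is testable without animal recordings.

## 1. The synthetic recording generator

The generator emulates the acquisition conditions typical of chronic rodent
studies: 16-channel single-shank arrays sampled at 24.4 kHz, sessions of a
few minutes, two recordings per week over eight weeks, six animals in a
rat-like group and fourteen in a mouse-like group.

A session is white Gaussian background noise (default SD 5 µV per channel)
plus linear superposition of stereotyped action-potential templates inserted
at homogeneous Poisson times with a 2 ms absolute refractory period per
unit. Two canonical template shapes are provided (biphasic and triphasic,
trough exactly on the detection-alignment sample); each template is scaled
so its peak-to-peak amplitude equals the requested value, and neighbouring
channels receive geometrically attenuated copies (default 0.1 per contact
step — at 50–100 µm contact pitch a unit is normally sub-threshold on its
neighbours). Optional broadband artifact transients (10–20× noise SD,
5–50 ms, on all channels simultaneously) emulate motion and connector
artifacts. A 1/f drift component exists behind a flag and is off by
default: the pipeline's band-pass removes it, and nothing in the emulated
studies characterizes noise spectra, so white noise is the defensible
default.

The longitudinal generator draws per-animal parameters once (expected units
per channel ~ Normal(1.3, 0.35), unit amplitude ~ Normal(110 µV, 15 µV)),
applies a multiplicative per-week decline (default 0.9) to both expected
yield and amplitude — the universal decline seen in chronic recordings —
and draws per-channel Poisson unit counts per session. An optional group
effect adds a constant to one metric's generative parameter for one group
within a chosen week range; with it absent the two groups are exchangeable,
which is the null configuration used for statistical calibration. All
randomness flows from a single seed through a counter-based fan-out
(`derive_seed()`), so any animal, week or session can be regenerated in
isolation and the same study spec always yields byte-identical output.

What the generator deliberately does not model: biophysical volume
conduction, electrode impedance, bursting or correlated firing, waveform
drift within or across sessions, and overlapping-spike interference beyond
linear superposition. Passing tests therefore demonstrate that the pipeline
recovers ground truth under clean, stationary conditions — they do not
certify performance on real recordings, where waveform drift and
non-Gaussian noise dominate failure modes.

## 2. The detection and sorting pipeline

Processing follows the standard chain, each stage a separate exported
function so alternatives can be spliced in:

1. **Band-pass 300 Hz – 3 kHz**, 4th-order Butterworth run forward and
   backward (`signal::filtfilt`) for zero phase shift.
2. **Common average reference**: the mean across working channels is
   subtracted from each working channel at every sample. This rejects
   common-mode noise exactly and preserves inter-channel differences
   exactly; it also leaks an attenuated, sign-inverted copy of every large
   spike onto all other channels (amplitude / n-channels), which the
   cluster-acceptance gate below must reject.
3. **Rule-based artifact removal** replacing blinded human review: samples
   exceeding 8× the channel's robust SD on at least half the channels
   simultaneously are excluded with ±5 ms padding, and channels whose
   robust SD exceeds 5× the median channel SD are flagged non-working.
   Parameters are logged with every run; the operation is idempotent.
4. **Noise estimation**: robust SD = median(|v − median(v)|)/0.6745 over
   retained samples. The plain sample SD is available behind a flag; the
   robust form is the default because the threshold should not inflate with
   the spike content of the trace.
5. **Detection** at 3.5× noise SD, negative-going by default (extracellular
   convention; configurable), first-crossing semantics, 1 ms lockout, with
   crossings inside excluded windows dropped.
6. **Snippets**: 12 samples before the crossing, the crossing sample, 24
   after — 37 samples. The crossing sample is counted; the phrasing "12
   pre to 24 post" does not say, so the inclusive reading is fixed here and
   used consistently by the generator, the pipeline and the tests.
7. **Clustering**, a documented stand-in for superparamagnetic sorting:
   snippets are realigned on their trough (the threshold crossing leads the
   trough by a trace-dependent 3–5 samples, and one-sample alignment jitter
   otherwise splits a unit into several mixture modes), projected onto
   their first three principal components, and fit with Gaussian mixtures
   for k = 1..5 selected by BIC (`mclust`). Accepted units must have ≥ 15
   members and a mean-waveform peak-to-peak amplitude ≥ 5× the channel
   noise level (2× robust SD) — the gate that rejects threshold-crossing
   noise clusters (~4.4× noise SD peak-to-peak) and common-average leak
   clusters. Finally, accepted clusters whose mean waveforms agree under a
   ≤ 4-sample shift to within the sampling noise of the two means (RMS
   difference ≤ 3 × noise SD × sqrt(1/nₐ + 1/n_b)) and whose amplitudes
   differ by < 25% are merged: residual one-sample trough dither otherwise
   yields duplicate clusters of the same unit. All steps are deterministic
   given the data.

The per-session product is a tidy channel table (unit counts, unit
amplitudes, noise level, detections per channel), which is also exactly the
shape the ground-truth generator emits — the pipeline and the generative
truth are interchangeable inputs to everything downstream.

## 3. The five metrics, channel windows and time bins

From a channel table, `compute_session_metrics()` returns:

1. per cent of working channels with ≥ 1 isolated unit;
2. mean units per working channel;
3. noise level: mean over working channels of 2× robust SD (µV);
4. unit amplitude: per-channel mean of unit peak-to-peak amplitudes,
   averaged over unit-bearing channels (µV);
5. SNR: each unit's amplitude over its own channel's noise level, averaged
   across units.

Metrics 4 and 5 are `NA` (not zero) for unit-free sessions, and stay `NA`
through group means. A channel counts as working when its noise level lies
in a configurable 2–60 µV band (the qualitative criterion — "impedances and
noise levels consistent with intact connections" — does not pin numbers;
these defaults catch dead and broken channels on the synthetic data) and an
externally supplied impedance veto is honoured if given.

To absorb implant-depth variance, metrics are computed on each animal's
most-active consecutive channel window — 10 channels for rat-like arrays,
8 for mouse-like — chosen once per animal as the contiguous window
maximizing the summed per-channel average unit count over the whole study,
ties resolved toward the smallest start index. The window is fixed per
animal rather than re-selected per session, matching the "highest sum of
average units over the study" reading. Weeks 1–2 are the acute range,
weeks 3–8 chronic, and total spans 1–8.

## 4. The nested general linear model

Each metric × time-range cell is tested with
`value = mean + group + animal(group) + residual`, least squares on
session-level observations (a per-animal-mean mode exists behind a flag).
Because sessions are repeated measures, the group effect is F-tested
against the animal-within-group mean square, not the residual — with g
groups and a animals that is F(g−1, a−g). With balanced sessions per
animal this is the exact test regardless of group-size imbalance; the
calibration test below confirms nominal size at the study's 6-vs-14
design. Observations missing for a metric are dropped listwise per fit;
zero animal-stratum variance is flagged degenerate rather than tested. The
suite runs 5 metrics × 3 ranges = 15 comparisons at a per-comparison
α = 0.05 with no multiplicity correction (matching per-comparison
reporting practice; Benjamini–Hochberg is available behind `fdr = TRUE`).
A group × time interaction is deliberately not included: the per-range
fits already localize effects in time, and the source analysis describes
group and time as the model terms.

## 5. The finite-element strain model

The model is a rectangular tissue block (5000 × 5000 µm in plan; 2500 µm
deep for rat, 1250 µm for mouse) with a silicon single-shank probe embedded
at its centre: 15 µm thick, 123 µm wide narrowing to 33 µm over the taper
(1500 µm rat, 750 µm mouse) plus a 50 µm tapering tip, inserted 2000 µm
(rat) or 1000 µm (mouse). Materials are isotropic linear elastic: brain
E = 6 kPa, ν = 0.43; silicon E = 200 GPa, ν = 0.27. The probe–tissue
interface is tied (shared nodes, no slip). Bottom and side outer tissue
surfaces are fixed; the probe cross-section at the brain surface is
prescribed u_x = 20 µm — the micromotion amplitude spanning respiratory
and vascular displacement — with u_y = u_z pinned there as well (a
skull-tethered headcap cannot move vertically relative to the skull;
`pin_lateral = FALSE` gives the x-only variant). The probe is modelled
flush with the brain surface; above the taper the width is constant at
123 µm (the rat's 2000 µm insertion minus 1500 + 50 µm of taper and tip
implies a 450 µm constant segment).

**Meshing.** No meshing library exists in the toolchain, so the package
meshes the geometry itself with a structured, graded tensor-product grid:
1D line sets snapped to the probe faces and graded geometrically from
`fine_size` (default 85 µm, matching the ~83 µm near-interface element
size being emulated) to `coarse_size` (500 µm) at the far field, each
hexahedral cell split into six tetrahedra. Cells below the XZ symmetry
plane use the y-mirrored split, so the mesh is exactly mirror-symmetric
about the plane containing the displacement. Elements are labelled probe
or tissue by hex-centroid membership in the tapered-shank solid, which
keeps the interface conforming and tied by construction. Defaults give
~31k tetrahedra (rat) and ~17k (mouse). The mesher is deterministic; the
`seed` argument exists only for interface symmetry.

**Solution and post-processing.** First-order (P1) tetrahedra with the
standard isotropic stiffness, assembled sparse and solved by Cholesky
factorization after eliminating constrained dofs (relative residual
verified < 1e−8). Strain is element-constant, ε = ½(∇u + ∇uᵀ); principal
strains come from the symmetric 3×3 eigendecomposition sorted descending
(ties are harmless under the symmetric equivalent-strain form); the von
Mises equivalent strain is

ε_e = 1/(1+ν) · √(½[(ε₁−ε₂)² + (ε₂−ε₃)² + (ε₃−ε₁)²])

with ν the **tissue** Poisson ratio everywhere, since reported strains are
tissue strains; probe elements are excluded from normalization maxima and
profiles by default. The two species' fields are normalized jointly by the
single maximum across both models, so the combined fields span [0, 1] with
exactly one element at 1. Profiles sample the normalized strain along +X
rays from the probe surface at the brain top (z = 0), probe mid-point
(z = insertion/2) and tip (z = insertion), every 10 µm to 500 µm (51 points
per depth; element values interpolated by inverse-distance weighting over
the 8 nearest tissue-element centroids), and the species comparison is the
Pearson correlation over the 153 paired points. The exact sampling scheme
behind the figure being emulated is unstated; this 3 × 51 grid is the
package's fixed choice. Internally everything is SI (meters, pascals);
µm values are converted at the interfaces.

**Verification.** The solver is checked against closed forms: the patch
test (an imposed linear displacement field is reproduced with constant
strain to 1e−10 relative), rigid-body translation and linearized rotation
(strain < 1e−12), a uniaxial bar against the exact stretch solution (< 1%,
including ε_e = axial strain for the uniaxial-stress state, which holds
for any ν by algebra), symmetry of a single-tet stiffness with a 6-mode
rigid null space, and linearity in both E and the prescribed displacement.

**What the model predicts, and a caveat.** With the Table-of-parameters
stiffness contrast (200 GPa vs 6 kPa) the shank behaves rigidly: a
beam-on-elastic-foundation estimate gives a flexural decay length of
~4 mm, well beyond either insertion depth, and the solved displacement
field confirms the probe translates by essentially the full 20 µm at all
depths. Consequently the strain concentrates where the rigid shank drags
tissue hardest — around the tip — and the joint maximum lands at the
mouse probe tip, consistent with where the emulated analysis reports its
maximum. The companion qualitative description of profile ordering (brain
top highest, mid-point negligible) is internally in tension with that
maximum location; this package reports both the argmax location and the
profiles and asserts neither ordering. The rat–mouse profile correlation
at default resolution is ≈ 0.999 (computed by `scripts/acceptance.R` and
the test suite), reflecting that the two geometries are near-scaled copies
under a rigid-translation load.

The tip corner is a re-entrant feature, so the *peak* strain grows slowly
under refinement rather than converging (the successive change shrinks —
from ~29% to ~16% per halving at coarse sizes — but does not vanish); the
normalized profiles, which divide by that peak's model, are far more
stable and carry the species comparison. First-order elements, the
voxel-like stepped approximation of the taper, static single-step loading,
and the absence of dura, glial scar, contact separation, viscoelasticity
and poroelastic coupling are the model's other deliberate limits.

## 6. Problem sizes and numerical choices

The test-suite study sizes are the package's chosen operating points: 6 s,
16-channel sessions for pipeline-recovery checks (50 seeded runs); 1 s
unit-free sessions for noise-metric calibration (100 runs); full
6-vs-14-animal, 8-week studies at ground-truth level for GLM size (1000
null studies) and power (200 replicates of a +2 units/channel acute-only
effect); FEM models at the default 85/500 µm mesh sizes. Tolerances in the
tests mirror estimator theory (e.g. 2% on robust-SD recovery at 10⁶
samples) or solver precision (1e−10/1e−12 on verification fixtures), not
tuned slack. Tie-breaks: window selection rounds sums to 9 decimals so
mathematically tied windows resolve to the smallest start index;
`which.max` then implements the documented tie-break. Degenerate inputs
(no working channels, < 2 animals per group, zero-variance profiles,
zero-load models) raise classed errors rather than returning numbers.
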