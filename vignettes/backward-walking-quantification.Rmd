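---
title: "Quantifying backward walking: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying backward walking: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkback)
```

## Scope

`walkback` quantifies backward walking in *Drosophila* at three levels of
observation: (1) leg kinematics from 2-D pose tracking of a single fly,
(2) stimulus-evoked activity in volumetric calcium imaging of the ventral
nerve cord or brain, and (3) population locomotion in an open arena under
optogenetic stimulation. Each analysis layer is paired with a synthetic-data
generator that produces inputs with fully known ground truth, so the whole
chain can be validated end to end without access to raw recordings.

This vignette explains the models behind each layer, the parameters that
matter, and the decisions taken where the procedures were underdetermined.

## Leg kinematics

### From landmarks to joint angles

A pose table provides five landmarks per leg (body–coxa, coxa–trochanter,
femur–tibia, tibia–tarsus, tarsal tip) plus two body-axis landmarks, each
with a tracking confidence. The analysis frame is x positive toward
anterior and y up; `read_pose_table()` flips image y so that dorsal and
anterior extremes are simple coordinate maxima. Joint angles are interior
angles in degrees in [0, 180] — the angle between the two segments meeting
at a joint — matching how such angles are conventionally plotted; the
body–coxa angle is measured against the posterior-pointing body axis.
Frames in which any defining landmark falls below the confidence threshold
(default 0.9) are set to `NaN` and excluded from all averages. Interior
angles are invariant to translation, rotation and uniform scaling of the
landmark set, so camera placement and magnification do not matter.

### Swing peaks and step segmentation

Steps are anchored on *swing peaks*: local maxima of the z-scored
tarsal-tip height. Manual proofreading of peak detection does not transfer
to a reusable package, so detection is parameterized instead: a peak must
have topographic prominence of at least 1.0 z-units and peaks must be at
least 50 ms apart (both exposed as arguments). The prominence criterion
rejects jitter on the ascending flank of a swing; the separation cap is
well below one step period at physiological step rates (< 20 Hz).

Windows are cut around each peak by a `step_window_spec`: total length,
frames before the peak, and a truncation margin. Two presets ship:

* `fig_long` — 300 frames (1.5 s at 200 fps) with the peak 40 frames in
  and an 8-frame (40 ms) margin; used for slow-flexion quantification.
* `fig_short` — 100 frames (0.5 s) with 49 frames before and 50 after the
  peak; used for step-geometry quantification.

When a neighbouring swing peak falls inside a window, the step is cut
`margin` frames short of that peak on the corresponding side; the same
8-frame margin is applied on both sides of both presets for uniformity.
Truncated tails are dropped from the per-position averaging denominator,
never zero-filled, so an averaged trace is unbiased wherever at least one
step contributes.

### Swing-interval inference on averaged steps

The swing interval of an averaged step is inferred from the vertical
velocity of the averaged tarsal-tip height. The height trace is smoothed
by a local-quadratic (Savitzky–Golay) filter, 11 points by default, and
differentiated; the swing spans the contiguous super-threshold rise
(velocity above 10% of its peak magnitude) leading into the swing peak
through the contiguous sub-threshold fall following it. The 10% fraction
and window length are exposed because "the inflection point" of a noisy
averaged trace is not operationally unique; on synthetic gaits the
inferred interval overlaps the true swing bout with Jaccard ≥ 0.8, which
is the property the tests enforce.

### Step geometry and angle metrics

For a step's tarsal-tip trajectory, AEP is the maximal-x point, PEP the
minimal-x point and DEP the maximal-y point. Step size is |AEP − PEP|;
swing-stroke amplitude is the distance from DEP to the closed segment
AEP–PEP (the closed segment matters: when DEP lies beyond the segment's
x-extent the distance is to the nearest endpoint). Both are invariant to
time reversal of the trajectory, so the same code serves forward and
backward walking.

Angle metrics: `joint_angle_range()` is max − min within a step;
`step_frequency()` is the reciprocal mean inter-peak interval;
`min_step_angle()` is the pre-peak minimum (stance flexion depth);
`flexion_slope()` fits an ordinary least-squares line from the position of
the maximal averaged angle to the window end and reports degrees/s.
`max_flexion()` returns the minimal angle reached after stimulus onset
(default window 1 s) *before the first re-extension*, defined as a rise of
more than 5° above the running minimum; the 5° threshold is exposed. This
rule makes a later, deeper dip after a partial re-extension irrelevant,
which is the intended reading of "maximal flexion before re-extension".

## Interleg coordination

A `footfall_pattern` is a legs × frames boolean matrix (`TRUE` = swing),
built either from per-frame annotations (passed through untouched) or from
tarsal-tip height. The height method thresholds the z-scored height at
0.5 z, removes bouts and gaps shorter than 3 frames, and then refines each
bout's boundaries by extending it outward along the strictly descending
flanks of the height trace and trimming frames already on the ground
plateau. The refinement step exists because a fixed z-threshold
systematically clips the low start and end of each swing arc; with it,
transitions on clean traces are recovered to within one frame of lift-off
and touch-down.

The co-swing index of a leg pair is |A∧B| / |A∨B| over a half-open frame
window — 1 for synchronous swing, 0 for strict alternation. Frames, not
seconds, are the integration unit, matching per-frame scoring of
high-speed video. `pairwise_summary()` scores all 15 pairs and groups them
into intrasegmental vs intersegmental (split by laterality by default);
the grouping is an argument because sensible poolings differ between
single-fly and cohort analyses.

## Calcium response mapping

### Model

One sample contributes an ordered set of identical sessions (default 10 ×
60 volumes at ~1 volume/s) under a fixed stimulus protocol (presets: one
20-s epoch at 10 s; two 1-s epochs at 10 s and 40 s). The analysis chain
is: concatenate sessions into a hyperstack (600 volumes); optionally apply
rigid integer-pixel motion correction (FFT phase correlation per volume
and z-slice against a reference volume); build a response kernel; compute,
for every voxel, the unnormalized demeaned cross-covariance with the
kernel at lags −5…+5 volumes (11 values); and reduce the 11 values to an
*activated* map (maximal positive value, 0 if none) and an *inhibited* map
(minimal negative value, 0 if none). Positive lag means the voxel follows
the kernel, so polysynaptically delayed responses surface at their delay,
readable via `peak_lag_map()`.

Two readings of the kernel–hyperstack pairing are possible: correlate a
session-length kernel within each session and combine, or tile the kernel
across the concatenated hyperstack. The package tiles (the stimulus
repeats identically every session), which is the only length-consistent
reading; with demeaning over the full series the two differ only through
edge terms. Covariances are left unnormalized (raw sums of demeaned
products); a `biased` (1/T) option rescales all values identically and
cannot change map topology.

### Kernels and dF/F

`roi_dff()` computes per-session ROI fluorescence, baselines it on
volumes 2–9 (early volumes, before the first stimulus at 10 s; volume 1
is skipped as a settling frame) and averages dF/F across sessions. ROIs
may be given as label masks, voxel index lists, or a polygon on a single
z-plane. `build_kernel()` averages such traces from strongly responding,
short-latency ROIs. For synthetic work, `make_gcamp_kernel()` generates
the template directly: the stimulus boxcar convolved with a normalized
difference of exponentials, default rise 0.2 s and decay 1.5 s
(slow-indicator, GCaMP6s-like dynamics at a 1-Hz volume rate), scaled to
peak 1.

### Thresholding maps

`threshold_map()` classifies responders at `sd_factor` (default 3) times a
robust background spread estimated by the median absolute deviation about
zero of the map's nonzero values — valid because responsive voxels are
sparse. On simulated scenes (16 384 voxels, 10 sessions, signal-to-noise
5–6) this recovers activated and inhibited cell voxels with precision and
recall above 0.9; that operating point was fixed from a pilot simulation
and is not tuned per dataset.

## Arena locomotion

Heading-projected speed is the dot product of the frame-to-frame
displacement (assigned the heading of the earlier frame, Δt from the
nominal 30 fps) with the heading unit vector: positive forward, negative
backward, sideslip zero. Backward distance accumulates |v|Δt over
stimulus-episode frames with v ≤ −1.5 mm/s (threshold exposed); forward
distance is the signed integral over the first 45 s with no threshold.
Both ignore arena position entirely — no wall or boundary correction —
and assume upstream tracking has resolved identities and heading sign.
The `flybowl9x5` schedule preset encodes nine 5-s episodes at 60-s
onset-to-onset spacing starting at 60 s.

## The synthetic-data generators

### What they emulate

* `simulate_gait()` — a phase-coupled hexapod gait: each leg's tarsal tip
  alternates between a stance segment on the ground plane (AEP → PEP when
  walking forward; reversed in backward mode) and a half-ellipse swing arc
  peaking at `swing_height`. Defaults: 2 Hz step frequency, duty factor
  0.5, tripod phase coupling ({LF, RM, LH} at phase 0, {RF, LM, RH} at
  0.5), ±0.4 mm stance extremes about each leg anchor, 0.2 mm swing
  height, 200 fps — the regime of a walking fly filmed at high speed.
  Inter-leg phasing during triggered backward walking is not established,
  so phase offsets are free parameters rather than a backward preset.
* `simulate_calcium()` — cells as disjoint voxel masks on a constant
  baseline (default 100), each following
  `F0 · (1 + a · kernel(t − d))` with signed amplitude `a` and lag `d`
  volumes, plus per-session additive Gaussian noise.
* `simulate_arena()` — responder flies reverse along their heading at a
  set speed (default 4 mm/s, safely above the 1.5 mm/s scoring threshold)
  during episodes and walk forward otherwise, with a Gaussian
  random-walk heading.

All generators derive per-entity random streams (per leg, per session,
per fly) from the master seed, so enlarging a dataset never perturbs the
entities already generated, and identical seeds give bit-identical data.

### Why gait angles are derived from limb geometry

An early design sketch drove the joints with free truncated-sinusoid
waveforms. That cannot simultaneously guarantee (a) that the stored
ground-truth angles are exactly consistent with the rendered landmarks
and (b) that the tip path has exactly the programmed AEP/PEP/DEP — and
both exactness properties are what make the generator useful as an
oracle. Instead the tip path is prescribed analytically and the remaining
joints follow from closed-form geometry: the coxa hangs vertically from
its anchor, the tarsus stands vertical above the tip, and the
femur–tibia pair closes the gap as a two-link chain via the law of
cosines (a closed form, not an iterative solver). Ground-truth angles are
the interior angles of that posture, so forward kinematics of the stored
angles reproduces the noise-free landmarks to machine precision, and the
programmed step size is recovered exactly. The price is that individual
joint-angle waveform shapes are emergent rather than directly
programmable; their periodicity and stance/swing phase locking are
preserved, which is what the kinematics metrics consume.

Landmark noise is additive Gaussian on leg landmarks only; the body-axis
landmarks stay noise-free as the angular reference.

### What passing tests do and do not show

The generators reproduce the *statistical structure the analysis
assumes*: periodic gait with known phases, cells that follow the kernel
exactly, flies that move exactly along heading. Real data violate all of
these — tracking errors are heavy-tailed rather than Gaussian, real
calcium responses vary across repetitions and adapt, real flies
translate while turning. Passing the recovery suites therefore shows the
*computations* are correct and well-conditioned at realistic noise, not
that the biological conclusions of any particular experiment are
automatic.

## Numerical choices and degenerate inputs

* Angles at coincident landmarks are `NaN` (logged), never extrapolated.
* Steps are clipped at trace and analysis-window boundaries; a step whose
  peak lies outside the analysis window is dropped and counted.
* Fewer than three distinct trajectory points make swing-stroke amplitude
  undefined (flagged), not zero.
* Fewer than two swing peaks make step frequency `NA` with a warning.
* Motion-correction shifts larger than a quarter of the slice are treated
  as implausible and clamped to zero; constant slices warn and stay put.
* The co-swing index of a window where neither leg swings is `NA`
  (flagged), not zero.
* Problem sizes in the shipped test and acceptance suites (10-s gaits at
  200 fps, 8 × 32 × 64-voxel scenes, 25-fly cohorts) were chosen as the
  smallest sizes at which every recovery property is comfortably
  non-marginal.

## Known limitations

* Kinematics are strictly 2-D sagittal; out-of-plane leg motion aliases
  into apparent angle changes, as with any single-camera setup.
* Motion correction is integer-pixel rigid translation per slice; slow
  drift is handled, deformation is not.
* The package computes per-fly and per-step summary tables but performs
  no hypothesis testing; those tables are intended for export into the
  user's statistical workflow.
* Heading sign errors (head/tail swaps) in arena tracks flip the sign of
  the projected speed and must be resolved upstream.
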