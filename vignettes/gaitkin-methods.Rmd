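---
title: "Methods: from pose tracks to gait parameters"
author: "gaitkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pose tracks to gait parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkin)
```

# The measurement problem

Markerless pose estimation turns a side-view video of a mouse on a
treadmill or ladder into per-frame `(x, y, likelihood)` coordinates for
labelled body parts. `gaitkin` extracts locomotor biology from those
time series: per-stride kinematic parameters on the treadmill, and
footfall (slip) events on ladder rungs. Everything operates in native
image coordinates — pixels, with the y axis pointing *down* — so all
height-like quantities are computed as `ground_y − y`, which reads
positive-up.

# Preprocessing

Two quality steps precede every pipeline, both exposed in
`analysisConfig()`:

- **Low-confidence interpolation** (`cleanLowConfidence`, default
  likelihood threshold 0.6). Samples below threshold are replaced by
  linear interpolation between the nearest flanking confident samples
  (nearest-value fill at the edges); likelihoods are preserved, making
  the operation idempotent. The threshold is an operating point of this
  package — tracking tools do not prescribe one — and 0.6 discards
  clearly uncertain detections while retaining partial occlusions.
- **Median smoothing** (`smoothSeries`, default window 5 frames at
  120 fps ≈ 42 ms). A running *median* rather than a mean, because
  tracking glitches (marker identity swaps) are heavy-tailed single
  frame spikes that a median rejects outright. Edges use shrinking
  windows so the series length is preserved.

# Treadmill model

The model of treadmill locomotion is deliberately minimal. During
stance the paw rides the belt, so the toe's camera-frame x velocity
sits in a tight mode at `−b` (the belt speed, px/frame); during swing
the toe moves forward. This bimodality drives three steps:

1. **Belt speed** (`estimateBeltSpeed`): `b` is minus the median of the
   smoothed central-difference toe velocity over negative-velocity
   frames, refined once by re-taking the median over frames below
   `−b₀/2`. The refinement discards near-zero swing-transition frames
   which otherwise bias the first median toward zero under pixel noise.
   If fewer than 20% of frames have negative velocity the animal is not
   walking (or the camera is mirrored) and the function aborts rather
   than guess.
2. **Adjustment** (`adjustCoordinates`): `x_adj(t) = x(t) + b·t` for
   every body part. A stance foot becomes stationary; the body
   progresses forward monotonically.
3. **Phase rule** (`classifyPhases`): frame `t` is stance iff
   `v(t) ≤ −b/2`, the midpoint of the bimodal velocity distribution.
   Runs shorter than `minPhaseFrames` (default 3 at 120 fps) are merged
   into their neighbour to suppress jitter micro-phases. The rule is the
   package's normative definition of phase; it is translation-invariant
   by construction.

**Cycle convention.** Strides run toe-off to toe-off (swing first, then
stance). Toe-off is the sharpest velocity transition and therefore the
most robust boundary to detect; the leading partial segment before the
first toe-off and the trailing segment after the last are excluded, so
every retained cycle is complete. A cycle whose toe never clears the
ground line during swing (clearance ≤ `dragTolerancePx`, default 3 px,
on every swing frame) is degenerate full-drag: only the
cycle-independent dragging parameters are reported for it.

# The 44-parameter schema

`kinematicParameterSchema()` fixes 44 named columns in five categories
— 16 joint-angle (mean/flexion/extension/amplitude for hip, knee,
ankle, MTP, each an interior angle of the marker chain), 12 endpoint
(step height, stride/swing/stance length, toe–crest distance statistics,
coordinate amplitudes, swing speeds, path length, swing-relative time of
peak height), 8 temporal (durations, stance/swing percentages summing
to 100, cadence, stance/swing ratio, stride speed), 6 variability (DTW,
below), 2 dragging (% of swing, duration). The schema is versioned:
names, order and category tags are identical for every input, and an
input with no complete cycles returns a zero-row table with the full
schema intact. Units are native pixels and seconds; an optional
pixels-per-cm factor can rescale lengths uniformly without affecting
classification or PCA, which standardize columns anyway.

**Spatial variability by DTW.** Successive limb endpoint trajectories
are compared by classic dynamic time warping: Euclidean local cost,
full window (strides are 20–80 frames, so no band is needed),
boundary-anchored, symmetric match/insert/delete steps. Cycle *i* is
compared against cycle *i − 1* on the x component, the y component, and
the 2-D trajectory; each cost is also reported normalised by its
alignment path length. Two numerical choices matter here:

- Each cycle's trajectory is **re-referenced to its onset**
  (`x_adj − x_adj(onset)`). The adjusted x advances one stride length
  per cycle; without re-referencing that offset would dominate the cost
  and mask the shape differences the measure is meant to capture.
- The first cycle (and any cycle following only degenerate ones) has no
  predecessor: its six DTW columns are structurally missing, and the
  analysis layer median-imputes them.

The DTW core is compiled (Rcpp), and a separate brute-force routine
enumerates every monotone alignment path explicitly; the test suite
verifies the two agree exactly on all ~600k sequence pairs of length
≤ 6 over a three-value alphabet.

# Ladder footfalls

In image coordinates a paw slipping below the rung line makes a
positive peak in raw y. The *deviation* algorithm detects these peaks
with a prominence threshold; **depth is defined as the prominence**, so
no rung-line calibration is needed. Two variants relax or tighten the
setup requirements: *threshold* (runs of excursion below a known rung
line — requires calibration) and *baseline correction* (a rolling
median, window 2 s, is subtracted first — for drifting cameras).

**Event width.** Prominence bases sit at the surrounding signal minima,
so the exact base-crossing is fragile under noise: a few pixels of
jitter move the crossing to wherever the baseline happens to dip. Event
onset/offset are therefore measured where the signal crosses
`peak − 0.9 × prominence` — just above the base — which tracks the
physical dip edges to within a few frames at 1 px noise while changing
nothing in the noiseless limit. Overlapping widths of adjacent peaks
are split at the valley between them, keeping events sorted and
non-overlapping.

The deviation detector is run deliberately permissive (default
prominence 10 px, configurable; no auto-calibration): over-detection is
expected and is resolved by `applyValidation()`, which applies
per-event accept/reject decisions from a file or an interactive pass.
`footfallSummary()` reports the three parameter families — number,
depth, duration — as count/mean-per-run, mean/total px, and mean/total
s respectively.

# Analysis layer

- **Outliers** (`removeOutliers`): a row is dropped iff any parameter's
  modified z-score `0.6745 (x − median)/MAD` exceeds 3.5. Median/MAD
  is robust to the heavy-tailed cycles of injured gait; zero-MAD
  columns are skipped with a warning, and missing values never trigger
  removal. Note the any-column rule is strict: on small homogeneous
  tables it can remove several rows, which is visible and reported.
- **Classification** (`runRandomForest`): individual step cycles are
  split 75/25 into train/test uniformly at random by seed, and a forest
  of 100 unlimited-depth Gini trees is fit to the training rows.
  Accuracy and the confusion matrix come from the held-out rows only;
  Gini importances (mean decrease in impurity) are normalised to sum 1.
  A fresh classifier is built per comparison. Missing values are
  median-imputed per column before the split.
- **PCA** (`runPCA`): parameters mix px, s, % and degrees, so
  correlation-matrix PCA (standardize, then eigendecompose) is the
  defensible choice. Loadings are eigenvectors scaled by the component
  standard deviations; explained-variance ratios are reported for all
  components, and `topFactorLoadings()` ranks parameters by absolute
  loading with ties broken by stable column order.

# The synthetic generator

`generateTreadmillTrace()` emulates the recording regime the pipelines
target — side-view, 120 fps, slow belt — with every generated quantity
recorded as ground truth. The toe is prescribed directly: backward at
`−b` px/frame during stance, forward along a smoothstep-x / half-sine-y
arc during swing (the sampled half-sine is renormalised so the apex
equals the configured step height *exactly*, making recovery tests
sharp). The rest of the chain (crest, hip, knee, ankle, MTP) is built
by forward kinematics from the hip with prescribed joint-angle
oscillations (knee interior angle sweeps 60–140° by default), so true
angle series exist in closed form. Dragging clamps the first
`dragFraction` of each swing to the ground line; the recorded truth is
the *realised* clamped-frame fraction, since rounding to whole frames
is what an ideal measurement would recover. Defaults (0.4 s strides,
duty factor 0.6, 2 px/frame belt, 25 px step height, 96 px stride at
roughly 30 px/cm) are mutually consistent so the simulated animal holds
station on the belt; if a user sets `strideLength` inconsistent with
`beltSpeed × strideFrames` the animal simply drifts, which is
physically valid for short bouts.

The trace opens with one full stance segment (so the first toe-off is
detectable) and emits a trailing swing only when it fits completely,
which makes the true complete-cycle count well-defined for any
duration. Gaussian pixel noise and near-one likelihoods with occasional
dips (1% of frames, only in noisy regimes) model tracking imperfection.

`generateLadderTrace()` keeps the paw at or above the rung line
(oscillation amplitude configurable) and injects half-sine dips of
stated onset, duration and depth — again renormalised so the maximum
excursion equals the configured depth exactly.

**What the generator does not emulate** — and hence what passing tests
do not certify about real data: out-of-plane paw motion and perspective
error, occlusion-driven correlated tracking failures, inter-stride
biological variability beyond pixel noise, compensatory multi-joint
coordination after injury, and ladder rung-to-rung geometry. The
generator validates the *computation*; instrument validation on real
recordings remains the user's task.

# Problem sizes and reproducibility

The test suite and the acceptance script use 1–5 s traces at 120 fps
(≈ 2–11 cycles each), 20 seeds for recovery properties, 10 ladder
traces × 5 dips for detection properties, and 40–60-cycle two-group
datasets for classifier/PCA checks — sizes chosen so the whole suite
runs in about a minute while every property is exercised across seeds.
Every stochastic component draws from a private RNG stream seeded from
its configuration (`.Random.seed` is saved and restored), so identical
configs reproduce traces, tables and classifications bit-for-bit.

The classifier's chance-level null check deserves a note. Two subtle
dependencies can push a correct pipeline systematically *below* 50%
held-out accuracy under label shuffling: cycles from the same trace are
similar (information leaks between train and test), and a permuted
*fixed* label multiset anti-correlates train and test class proportions
— if the training split happens to hold more of class a, the test split
necessarily holds fewer, and a forest that falls back to the training
majority is then wrong more than half the time. The null check
therefore uses one complete cycle per trace (independent rows) and
draws labels iid with probability ½; under iid labels the number of
correct held-out predictions is exactly Binomial(n, ½) for *any*
classifier, making the binomial interval an exact reference.

# Design notes and limitations

- Frame indices are 1-based inside R (the language's idiom); the
  on-disk text dialect keeps the conventional 0-based frame-index
  column, and round-trips are bit-identical.
- Only the three-header-row text dialect is read; HDF5 pose containers
  are not supported — convert to CSV first.
- Single-side camera: no left–right coupling, no bilateral coordination
  indices, no forelimb chain.
- The prominence threshold is a per-setup choice (it is a pixel
  quantity and depends on magnification); the package exposes it in
  config and performs no auto-calibration.
- Group-level inferential statistics (ANOVA families, post hoc tests)
  are out of scope; export the parameter table to your statistics
  environment of choice.
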