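---
title: "Multi-sensor activity recognition: models, parameters and design choices"
author: "MultiSenseHAR"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Multi-sensor activity recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Home-monitoring systems recognize elementary human activities from very
different sensors: wearable electromyographs, instrumented insoles,
accelerometers, or an ambient camera. Which sensor recognizes which activity
best is an empirical question, and answering it requires one pipeline that
treats every modality the same way downstream: fixed-length feature vectors,
one classifier, one set of evaluation statistics.

`MultiSenseHAR` implements that pipeline for twelve elementary activities —
six movement families, each with a forward phase (`a`) and its return phase
(`b`): squat down/up (1a/1b), sit down / stand up (2a/2b), reach the arm
forward / return (3a/3b), reach upward / return (4a/4b), bend the trunk /
straighten (5a/5b), and a single right / left step (6a/6b) — observed
simultaneously by four sensors: 8-channel surface EMG at 2 kHz (sensor code
B), 64-sensel plantar pressure at 100 Hz (C), side-view grayscale silhouette
video at 25 fps (D) and a triaxial sternum accelerometer at 100 Hz (E).

Because no recordings of this kind are openly available, the package ships a
synthetic cohort generator whose output has the statistical structure the
analysis assumes. Every downstream stage is therefore testable end to end,
from raw streams to confusion matrices, without any external data.

# The synthetic cohort

`generateCohort()` simulates, per subject, a full recording session: a
stationary lead-in of 10 s (standing still; used for accelerometer offset
estimation), then a randomized-order sequence of activity repetitions
separated by 1 s rest gaps, then 2 s of trailing quiet.

**Activity templates.** `activityArchetype()` maps each (activity, sensor)
pair to a deterministic template over the normalized activity phase
$p \in [0,1]$, built from smooth Gaussian bumps. Families differ in their
channel weights (which muscles fire, which foot regions load, which way the
sternum accelerates) and in their envelope timing; the `b` variant of a
movement is the time reversal of its `a` variant (the envelope is
deliberately asymmetric in time so the reversal is distinguishable), except
for stepping, where 6a/6b are left/right mirrors with the stepping side
leading in time. No biomechanical fidelity is claimed — only the statistical
structure matters: all 12 templates are pairwise distinct on every sensor,
which the test suite checks exhaustively.

**Randomness model.** Per repetition, the duration is log-normal around an
activity-specific median (defaults 1.3–2.2 s, `sdlog` 0.18, clamped to
[0.6, 4] s) — chosen so the pooled duration histogram has its bulk below 2 s
and the standard 1.6 s analysis window covers most repetitions. Per subject,
a log-normal amplitude multiplier (`sdlog` 0.15) scales each sensor's
archetype, emulating inter-subject amplitude variability, and white Gaussian
noise is added per sensor (defaults: EMG 0.05, pressure 0.03, acceleration
0.03 in archetype amplitude units; video 0.005 intensity units). Each
subject owns an RNG substream derived from the cohort seed by fixed offsets,
so equal seeds give byte-identical cohorts regardless of evaluation order.

**Silhouette video.** Frames show a textured two-blob body (torso + legs)
over a static background; the texture is fixed in body coordinates so the
pattern translates rigidly with the body. During a repetition the body
oscillates (0.48 s period, amplitude ≈ height/16 px, peak speed ≈ 2
px/frame) along an activity-specific pair of axes — one axis for the first
half of the repetition, another for the second, with the twelve (first,
second) axis pairs pairwise distinct and `a`/`b` variants swapping their
axes. Between repetitions the silhouette stands still. Video is rendered
lazily (a `SilhouetteVideo` renderer closure) so a session never
materializes in memory; per-frame noise is seeded by frame index, keeping
lazy rendering deterministic and order-independent.

What the generator does **not** emulate: realistic muscle synergies or EMG
spectra, continuous gait, posture-dependent pressure redistribution, camera
perspective, occlusion, lighting changes, or background clutter. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
discriminative under controlled conditions — not that these accuracies
transfer to real recordings.

# Windowing

Activities differ in duration across repetitions and subjects, so feature
vectors are cut to a fixed window of `W` seconds (`windowSpec()`, default
1.6 s). `durationHistograms()` supports choosing `W` by inspecting the MIN/MAX/AVG/ALL and per-activity
histograms of performance time (0.1 s bins by default); the choice itself
stays manual and configurable.

The window anchor is a design choice the analysis leaves open: this package
centers the window on the segment midpoint, so repetitions shorter than `W`
are flanked symmetrically by their quiet context, and longer repetitions
contribute their central sub-span (`alignment = "start"` is available). The
clip always contains exactly `round(W * rate)` samples per channel —
dimension never depends on segment duration.

# Per-sensor feature chains

All chains end at 25 Hz, giving `n_channels * round(25 W)` features
(320 EMG, 240 pressure, 120 acceleration for `W = 1.6`):

* **EMG (B):** full-wave rectification → 0.1 s centered moving average →
  division by the subject's global EMG maximum (over all of that subject's
  measurements of all activities) → amplitude normalization to the unit
  interval over the concatenated 8 channels → linear-interpolation
  resampling to 25 Hz → concatenation EL1..EL4, ER1..ER4.
* **Pressure (C):** sensel-to-region averaging (heel/center/front per foot;
  the sensel map is configuration — the default is a 4×8 grid per insole
  with rows 1–3 front, 4–5 center, 6–8 heel) → 0.3 s moving average →
  subject normalization → unit interval → 25 Hz → L1..L3, R1..R3.
* **Acceleration (E):** per-channel offset subtraction (offsets = mean over
  the 10 s stationary lead-in) → 0.2 s moving average → subject
  normalization (by the maximum absolute value) → unit interval → 25 Hz →
  X, Y, Z.

Numerical choices worth stating: the moving average shrinks its window at
clip boundaries (length-preserving; constants pass through); resampling is
plain linear interpolation at the target timestamps $k/25$ s with no
anti-alias filter (the preceding moving averages already smooth);
normalization happens **before** resampling, in the chain's fixed order,
and is *not* repeated afterwards — interpolation can therefore shave the
post-resampling maximum marginally below 1. The unit-interval step is
implemented as division by the maximum, so exact zeros are allowed (a silent
EMG channel) and offset-corrected acceleration retains its negative
excursions; what the container guarantees is values ≤ 1 with a strictly
positive maximum. The subject-wise normalization makes features exactly
invariant to scaling a subject's entire raw signal, which is tested.

# The silhouette motion descriptor

For each video clip (40 frames at `W = 1.6`), every interior frame with both
neighbouring flow fields contributes one 8-bin direction histogram, giving
`(N − 2) × 8 = 304` features:

1. **Horn–Schunck optical flow** between consecutive frames: the classical
   Jacobi iteration (zero initialization) for the flow minimizing
   brightness-constancy error plus $\alpha^2$ × smoothness. Defaults
   $\alpha = 1$, 100 iterations. One subtlety: $\alpha$ trades off against
   squared image gradients, so its conventional value is tied to the 8-bit
   intensity scale; frames here live in [0, 1] and are scaled by 255
   internally. The brightness-constancy residual decreases over early
   iterations (tested), and a 1 px translation of the textured body is
   recovered to ≈ 0.9 px.
2. **5×5 median filtering** of both flow components (shrinking windows at
   the borders), removing flow outliers.
3. **Motion binarization**: pixel moving iff flow magnitude strictly
   exceeds the threshold `T` (constant for all subjects and activities;
   default 0.5 px/frame, configurable — the synthetic motion is designed
   at ≈ 2 px/frame peak so the default sits well below true speeds).
4. **Moving silhouette**: the two masks around frame $n-1$ are combined —
   union by default, intersection by option, since either reading of a joint
   moving region is defensible — and enclosed holes are filled.
5. **Contour thickening**: the band is the mask minus its erosion by a
   9×9 square, i.e. the inner ≈ 4 px boundary ring.
6. **Direction histogram**: flow vectors on the band are binned into eight
   45° sectors, B1 centered on 0° and proceeding counter-clockwise in
   display space (x rightward, y upward on screen), with the first bin
   wrapping around zero (337.5°–22.5°).
   Aggregation weights each vector by its magnitude — the descriptor
   aggregates motion *vectors*, not moving pixels (count weighting is
   available), and each histogram
   is normalized to sum to 1. A band without motion yields the all-zero
   sentinel; a clip with no motion at all raises a degenerate-vector error
   rather than fabricating a feature.

The descriptor passes a rotation-consistency property (rotating all flow
vectors by 45° permutes the bins cyclically) and recovers all eight
bin-center translation directions on synthetic clips.

# Classification and evaluation

Classification is k-NN under the Manhattan metric. The neighbourhood size is
selected by leave-one-out on the learning set (`looSelectK()`); `k = 1` is
the expected optimum for this kind of data and is the pipeline default.
Tie-breaks are fixed deterministically: equal distances resolve to the lower
training index, vote ties to the class of the nearest tied member. Distances
are compared after rounding to 12 significant digits so that mathematically
equal distances are recognized as ties regardless of floating-point
summation order — without this, the deterministic tie-break silently depends
on the arithmetic route.

The learning/test split (`splitTrainTest()`) draws `nTrain` segments without
replacement, stratified proportionally by activity (largest-remainder
quotas). This package stratifies by default (a plain uniform draw is
available) and uses the same seeded
segment split for every sensor so sensor comparisons are paired. Per-subject
rates are computed on the test split only — training rows have no honest
prediction.

Evaluation computes the recognition statistics: per activity $a$,
$R_a = 100 P_a / W_a$ (correct / performed repetitions, pooled over
subjects) with the weighted dispersion

$$U = \sqrt{\frac{\sum_i w_i (x_i - R)^2}{\frac{n-1}{n} \sum_i w_i}},$$

whose center is deliberately the *pooled* rate $R$, not the weighted mean
of the group rates (these differ): it measures how far each group sits
from the aggregate figure being reported. Weights are
repetition counts; groups with zero repetitions are excluded from $n$, since
zero-weight groups are undefined in the formula; with fewer than two groups
the statistic is `NA`. The same form yields the inter-subject dispersion of
the overall rate, the per-subject inter-activity dispersions, and the
activity-weighted overall dispersion. Confusion matrices are
column-normalized percentages (columns = performed activity, summing to 100
before display rounding) with $R_a$ on the diagonal. `writeReportTables()`
emits the per-activity, per-subject and confusion tables in the published
shapes, rounded to one decimal for display while the objects keep full
precision.

On cohorts with heterogeneous subject error rates, per-activity recognition
and its dispersion are negatively rank-correlated (a property check at fixed
seed): a poorly recognized activity is typically poorly recognized because
*some* subjects perform it idiosyncratically, which is exactly what the
weighted dispersion measures.

# Problem sizes used by the checks

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes that still exercise every code path meaningfully: the
end-to-end recognition check uses 6 subjects × 12 activities × 10
repetitions (720 segments, 80×64 px video) with zero noise, where the three
biosignal sensors classify the held-out half perfectly and video reaches at
least 95%; noise monotonicity uses 4 subjects × 6 repetitions at noise
levels {0, 0.5, 2} × three seeds (biosignal sensors); direction recovery
uses full 180×144 px frames; the acceptance script's cohort is 5 subjects ×
8 repetitions with the default noise levels. The full default configuration
(20 subjects, 19–46 repetitions, 2 kHz EMG) generates multi-gigabyte
sessions and is intended for scripted use on adequate hardware, not for the
test suite.

# Known limitations

* The synthetic archetypes encode qualitative activity structure only;
  absolute accuracies on this cohort say nothing quantitative about real
  sensors.
* Horn–Schunck underestimates large displacements (> ~2 px/frame with the
  default texture); the generator keeps speeds in its linear range.
* The silhouette teleports between its rest and active positions at segment
  boundaries; windows centered on segment midpoints rarely see this, but
  start-aligned windows of short segments may include one artifact frame
  pair.
* `EBImage` erosion treats pixels beyond the border as foreground, so
  contour bands of silhouettes touching the frame edge are thinner there;
  the generator keeps the body away from the borders.
* No sensor fusion: the design question is how sensors compare
  individually, so the pipeline evaluates them individually.
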