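---
title: "Markerless gait analysis from two cameras: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless gait analysis from two cameras: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereogait)
```

# The measurement problem

Optoelectronic marker-based motion capture is the laboratory standard for
gait analysis, but it needs dedicated hardware, trained personnel and
markers glued to the subject. A cheap alternative: two consumer webcams film
the walking subject, a pose-estimation network (the 18-keypoint COCO body
model, as produced by OpenPose) locates the skeletal joints in every frame
of each video, and classical stereophotogrammetry turns the two 2D keypoint
streams into 3D joint-center trajectories. From those, the spatio-temporal
parameters that clinicians actually read — step length, stance time, swing
time — can be extracted.

`stereogait` implements this measurement chain end to end, together with
the metrological machinery needed to validate it against a marker-based
reference: temporal synchronization, rigid spatial alignment, per-node RMS
trajectory errors, Bland-Altman agreement, and a two-level factorial ANOVA
over the three setup factors that plausibly drive accuracy (gait direction,
camera distance, video resolution). Because no public dataset pairs
two-camera keypoint streams with a reference system, the package also ships
a synthetic gait laboratory with known ground truth; every pipeline stage is
tested against it.

# The pipeline

1. **Triangulation.** Keypoints from the two calibrated cameras are
   undistorted (Brown-Conrady model inverted by fixed-point iteration,
   tolerance 1e-10, at most 50 iterations) and triangulated by the linear
   DLT construction on normalized coordinates with camera matrices `[I|0]`
   and `[R|t]`. The homogeneous least-squares solution is exact on
   noise-free projections (the test suite checks 1e-6 m over 1000 random
   points in a 3 x 2 x 2 m working volume). A joint is valid only when both
   cameras observed it and the rays were not near-parallel. DLT was chosen
   over midpoint or polynomial triangulation because it is the generic
   workhorse of calibration toolboxes and is exactly testable.
2. **Gap handling and filtering.** Dropout runs of at most 5 frames are
   bridged by linear interpolation; longer gaps stay invalid and invalidate
   the gait cycles they overlap. All coordinates of both systems are then
   low-pass filtered with a zero-lag 2nd-order Butterworth at 10 Hz,
   applied forward and backward with odd-reflection padding of
   `3 * (order + 1)` samples and steady-state initial conditions.
3. **Synchronization.** No hardware trigger links the cameras to the
   reference system, so the subject taps the right wrist on the right hip a
   few times before walking. The wrist-hip distance series of the two
   systems (reference first downsampled to 30 Hz by cubic splines) are
   low-passed at 3 Hz and slid against each other; the integer lag
   maximizing the normalized cross-correlation of the mean-removed signals
   wins, with ties broken toward zero. The signals are z-scored globally
   and zero-filled outside the valid overlap rather than renormalized per
   overlap: per-overlap normalization rewards extreme lags where only a few
   noisy samples remain. Sub-frame refinement is deliberately absent — at a
   30 Hz camera rate an integer lag leaves at most 17 ms of residual
   offset, far below the tolerances of the parameters of interest, and
   clock drift over a 6 s recording is negligible.
4. **Spatial alignment.** One global rigid transform (Kabsch: SVD of the
   centered cross-covariance with the determinant correction, so a proper
   rotation is guaranteed even for degenerate or mirrored configurations)
   maps the triangulated skeleton from the camera frame into the laboratory
   frame, fitted over all valid frame x node correspondences of the 13
   evaluation nodes. A single transform per recording, not per frame: the
   relation between the two systems is a fixed change of coordinates, and
   letting it vary would absorb genuine measurement error.
5. **Gait events.** The speed of each ankle,
   `v_i = f * ||p_i - p_(i-1)||`, is smoothed by a zero-phase moving
   average (default effective window: 24 samples, 0.8 s) and fed to a
   two-threshold automaton: swing when the speed exceeds the high
   threshold, stance when it drops below the low one, state held in
   between. The thresholds are calibrated per recording: the high one is
   the nearest-rank 65th percentile of the sorted valid smoothed speeds of
   the active gait span, the low one exactly 80% of it. Only complete
   steps survive: cycles are delimited by heel strikes, and the first/last
   cycle is dropped when the recording enters/exits in swing (the classic
   four boundary cases).
6. **Parameters and evaluation.** Heel strike opens a cycle; stance runs to
   the toe-off, swing to the next heel strike; step length is the
   ground-plane distance between a heel-strike ankle position and the
   opposite foot's previous one. Markerless and reference step records are
   paired greedily by nearest heel-strike time within 0.25 s. The
   evaluation layer reports per-node RMS distances (mm) after a fresh
   Kabsch alignment, RMS parameter errors (step length in cm, times in s),
   Bland-Altman bias and 1.96-SD limits of agreement, and per-effect
   partial F tests of the factorial model
   `xi = b0 + b1 x1 + b2 x2 + b3 x3 + b12 x1 x2 + e` with effects coded
   -1/+1 (under the balanced design all sums-of-squares conventions
   coincide; subject is pooled, not modeled).

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Butterworth cut-off | 10 | Hz | Above voluntary movement bandwidth, below keypoint jitter |
| Speed smoother window | 24 | samples | First spectral null at 1.25 Hz at 30 Hz sampling (see below) |
| High threshold rank | 0.65 | — | Percentile of sorted smoothed speeds |
| Low/high threshold ratio | 0.8 | — | Hysteresis band against residual noise |
| Gap bridge limit | 5 | frames | ~0.17 s; longer dropouts are not plausibly linear |
| Step match tolerance | 0.25 | s | Below half a step period at comfortable cadence |
| Sync search range | 90 | frames | 3 s; generous for software-triggered recordings |

## The smoother window

The speed smoother is specified in the source method as a moving average
with a "period of 12 samples" whose first transfer-function zero at 30 Hz
sampling is 1.25 Hz. These two statements conflict: a 12-tap average at
30 Hz has its first null at 2.5 Hz. The spectral statement is the testable
one, so the default is an effective 24-sample window (a symmetric 25-tap
kernel with half-weight endpoints, DC gain exactly 1), whose first null is
exactly 1.25 Hz; the 12-sample reading remains available through the
`window` argument. `first_transfer_zero(fs = 30)` verifies the null by
evaluating the kernel's frequency response on a dense grid and refining the
first sign change by root finding.

## Threshold calibration span

Thresholds are to be calibrated "from a complete gait test". A recording
here starts with a standing synchronization prologue several seconds long;
feeding those near-zero speeds into the percentile would collapse both
thresholds. The calibration span is therefore the active gait interval:
from the first to the last frame where either foot's smoothed speed exceeds
30% of its maximum. The detection automaton still runs over the entire
recording.

# Known limitation: the stance/swing split is biased

A property worth stating plainly, because the test suite documents it. With
a 0.8 s smoothing window, the smoothed swing pulse of an ankle (swing
duration ~0.5 s) is wider than one stride (1.2 s at 100 steps/min), so the
65th-percentile threshold lands near the flat top of the smoothed pulse,
where the crossing slope is small. Consequences, measured on noise-free
synthetic walks:

- stride time and step length are recovered essentially exactly (the
  stance ankle is stationary, so a late-detected heel strike still reads
  the correct position);
- heel strikes and toe-offs are both detected late by a few frames, and
  the stance/swing *split* carries a systematic bias of roughly 1-2 frames
  (0.03-0.07 s) that no choice of calibration span removes;
- the bias is identical for the markerless and the reference stream, so
  *between-system* parameter errors — the quantities the evaluation layer
  reports — are unaffected by it.

This is a property of the percentile-plus-hysteresis detector itself, not
of its implementation; it varies with cadence and stance fraction because
those move the threshold relative to the pulse plateau. Consumers who need
absolute event times at sub-frame accuracy should use a narrower smoother
(at the price of noise immunity) or an event definition anchored to the
speed pulse edges.

# The synthetic laboratory

`simulate_walk()` builds a deterministic kinematic avatar: the stance ankle
is stationary; the swing ankle advances two step lengths along the path
with the smooth profile `s(tau) = 2L (tau - sin(2 pi tau) / (2 pi))` and a
5 cm sinusoidal lift; the pelvis advances at the mean gait speed with a
2 cm vertical oscillation at stride frequency; knees interpolate hip to
ankle with a forward bias peaking mid-swing; arms swing anti-phase by
20 degrees with a 12-degree forward rest flexion (so the wrist sits ~0.26 m
from the hip and the tap gesture is observable); the face keypoints ride on
the neck. The subject starts from a staggered step-stance — every swing
advances a full stride length, keeping the speed pulses homogeneous — and
stands for 0.6 s at the end of the walkway while the cameras keep rolling,
so recordings close in double support. Walks default to 5 steps of 0.60 m
at 100 steps/min with a stance fraction of 0.60 (the canonical comfortable
gait of two ~24-year-old adults, which the source study leaves
unquantified), giving ~6.5 s recordings.

`render_reference()` samples the ground truth at 100 Hz and adds 0.2 mm
isotropic noise, the stated reconstruction error of the reference
optoelectronic system. `render_cameras()` places two cameras on a bar
(baseline 1.0 or 1.8 m) at 2.3 m height, aims both at the mid-path point
(which fixes the pitch), scales a native 1920 x 1080 / f = 1200 px sensor
model to the HR (1312 x 736) or LR (640 x 480) mode — resolution acts on
the intrinsics, never on images — projects every joint with lens
distortion, delays the streams by a configurable integer lag, and corrupts
the keypoints with a two-component error model that mirrors how
pose-estimator output actually fails:

- **systematic landmark displacement**: a constant 3D offset per joint,
  drawn once per recording (SD 12 mm) — the estimator's skeletal model
  does not coincide with marker-derived joint centers — with a larger
  component (25 mm) on far-side joints during diagonal walks, because
  occluded landmarks are estimated rather than observed, which biases
  them;
- **jitter**: AR(1)-correlated pixel noise (marginal SD 0.5 px,
  frame-to-frame correlation 0.9 — estimator output drifts smoothly, it
  does not flicker), with 1 px extra on occluded joints, plus random
  dropout and confidences drawn from U(0.4, 1).

The decomposition matters: trajectory RMS is dominated by the offsets
(which rigid alignment only partially absorbs), while gait-event detection
only sees the jitter through the speed signal. A single white-noise knob
cannot reproduce both error scales at once.

What the simulator does *not* emulate — and what passing tests therefore do
not establish about real data: soft-tissue and clothing artifact,
systematic (non-zero-mean) keypoint displacement such as OpenPose's
tendency to place joint centers differently from marker-derived ones,
multi-person scenes, rolling-shutter and exposure effects, and genuinely
pathological gait. The simulator's role is to verify the measurement chain
against a known truth, not to certify field accuracy.

`simulate_batch()` enumerates the 2 (direction) x 2 (baseline) x 2
(resolution) design with 3 replicates and 2 subjects (statures 1.73 m and
1.82 m), 48 recordings, each with a distinct derived seed. On this batch
the mean node RMS orders as diagonal > straight and LR > HR, driven by the
occlusion noise and by the coarser angular resolution of LR pixels; the
worst cell (diagonal, 1.0 m, LR) occasionally defeats the gesture
synchronization altogether, in which case the pipeline still reports
trajectory errors and marks the step metrics absent.

# Numerical choices and degenerate inputs

- Rotations are validated to 1e-9 orthonormality; calibration files with up
  to 1e-6 drift are re-orthonormalized by polar decomposition, anything
  worse (or a reflection) is rejected.
- Triangulation flags rays as degenerate when the two smallest singular
  values of the DLT system are within 1e-12, and when the solution lands
  behind either camera.
- The automaton's initial state compares the first speed sample to the
  high threshold, which is unbiased for recordings starting mid-stance or
  mid-swing; the four-case trimming makes the choice immaterial for
  complete cycles.
- An all-equal speed histogram (no gait dynamics) and a flat gesture signal
  (no taps) are errors, not silent defaults.
- Test problem sizes: 1000-point triangulation oracles, 200-400-point
  Monte-Carlo noise checks, 6 noise-free pipeline configurations, the full
  48-recording factorial batch, and 2000 null simulations for the ANOVA
  type-I calibration; the complete suite runs in about half a minute on one
  CPU.

# Interfaces

The package is the interface: `run_recording()` for one in-memory
recording, `pipeline_run()`/`pipeline_simulate()` for the file-based
chain with per-stage checkpoints, `batch_error_table()`/`batch_anova()`
for the factorial analysis. A thin command-line wrapper over exactly these
functions ships in `inst/cli/stereogait.R` with `simulate`, `run` and
`anova` subcommands.
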