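# stereogait

Markerless gait analysis from two consumer cameras, with the metrology to
know whether to trust it.

A pose-estimation network (OpenPose's 18-keypoint COCO body model) locates
skeletal joints in every frame of two synchronized videos; `stereogait`
turns those 2D keypoint streams into clinical gait measurements and
quantifies their accuracy against a marker-based optoelectronic reference:

- **stereo reconstruction** — Brown-Conrady undistortion and linear (DLT)
  two-view triangulation of every joint into 3D, from a standard
  calibration file (intrinsics, distortion, relative pose);
- **synchronization and alignment** — the inter-system time offset is
  recovered from a wrist-to-hip tap gesture by cross-correlating the
  wrist–hip distance series of the two systems; one global Kabsch
  roto-translation then maps the reconstruction into the laboratory frame;
- **gait events** — each ankle's speed `v_i = f · ‖p_i − p_{i−1}‖` is
  smoothed by a zero-phase moving average (first spectral null at 1.25 Hz
  for 30 Hz video) and segmented into stance (0) / swing (1) by a
  hysteresis automaton whose thresholds are calibrated per recording: the
  swing threshold is the nearest-rank 65th percentile of the sorted
  smoothed speeds, the stance threshold 80% of it; only complete steps
  (four boundary cases) yield parameters;
- **parameters** — step length, stance time, swing time per complete cycle;
- **evaluation** — per-node RMS trajectory error (mm) after optimal rigid
  alignment of the 13 comparable nodes, RMS parameter errors over
  time-matched steps, Bland–Altman bias and limits of agreement, and the
  two-level factorial ANOVA
  `ξ = β₀ + β₁x₁ + β₂x₂ + β₃x₃ + β₍₁,₂₎x₁x₂ + ε`
  over gait direction, camera distance and video resolution;
- **a synthetic gait laboratory** — a kinematic walking avatar with exactly
  known step length, cadence, stance fraction, events and inter-system lag,
  rendered both as a 100 Hz reference stream and as two 30 Hz keypoint
  streams (OpenPose JSON dialect) with lens distortion, systematic
  landmark offsets, correlated jitter, occlusion effects and dropout.

## Worked example

Simulate one recording at the strongest setup (1.8 m baseline, high
resolution, straight path, 12-frame inter-system lag) and run the full
measurement chain:

```r
library(stereogait)
set.seed(1)
cfg   <- gait_config(step_length = 0.60, cadence = 100, n_steps = 5, seed = 42)
gt    <- simulate_walk(cfg)
scene <- scene_config(baseline = 1.8, resolution_mode = "HR", lag_frames = 12)
rec   <- render_cameras(gt, scene)
ref   <- render_reference(gt, scene)
rep   <- run_recording(rec$seriesA, rec$seriesB, rec$rig, ref)
print(rep)
#> Gait report: lag -12 frames; mean node RMS 30.5 mm; 3 matched steps
#>   RMS errors: step length 6.60 cm, stance 0.027 s, swing 0.027 s
```

The report says: the 12-frame delay of the camera streams was recovered
exactly (the markerless stream is shifted back 12 frames to meet the
reference); after rigid alignment the 13 node trajectories agree to a mean
RMS of 30.5 mm; and over the three complete, time-matched steps the two
systems differ by 6.6 cm RMS in step length and 27 ms in stance and swing
time. Per-node errors and the step table are in the report object:

```r
print(rep$node_report)
#> Node RMS trajectory error (mm)
#>      Neck RShoulder    RElbow    RWrist LShoulder    LElbow    LWrist      RHip
#>      25.4      29.0      29.3      29.8      40.0      20.4      38.2      25.0
#>     RKnee    RAnkle      LHip     LKnee    LAnkle
#>      40.5      37.2      17.4      32.8      31.9
#> mean 30.5 mm, SD 7.3 mm over 13 nodes

rep$steps_op[, c("foot", "heel_strike_time_s", "step_length_m",
                 "stance_time_s", "swing_time_s")]
#>    foot heel_strike_time_s step_length_m stance_time_s swing_time_s
#> 2 right           4.100000            NA     0.6333333    0.5666667
#> 1  left           4.733333     0.6788144     0.5666667    0.6333333
#> 3 right           5.300000     0.5498951     0.6666667    0.5333333
```

(The first step has no length: its opposite-foot predecessor fell before
the first detected heel strike.)

The factorial experiment of the validation design — 2 directions × 2
baselines × 2 resolutions × 3 replicates × 2 subjects = 48 recordings —
runs as:

```r
manifest <- simulate_batch(replicates = 3, subjects = 2, seed = 11)
tab      <- batch_error_table(manifest)   # one row of errors per recording
batch_anova(tab)$rms_mm                   # which factors drive the error?
```

On this batch the trajectory error grows for diagonal walks (occlusions),
shrinks with the wider baseline and with the higher resolution, and shows
a direction × distance interaction — every main effect highly significant,
which is the qualitative fingerprint this class of two-camera systems is
expected to show.

A thin command-line wrapper over the same functions is installed at
`inst/cli/stereogait.R` (`simulate`, `run`, `anova` subcommands); the
`run` subcommand consumes two OpenPose JSON directories, a calibration
JSON and a reference trajectory CSV, and checkpoints every stage.

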