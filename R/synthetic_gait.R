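# Ground-truth generator standing in for the laboratory: a kinematic walking
# avatar with known spatio-temporal parameters, a 100 Hz marker-based
# reference renderer and a two-camera 30 Hz keypoint renderer with noise,
# dropout, resolution scaling and a known inter-system time offset.

#' Gait configuration for the walking simulator
#'
#' @param step_length Step length in meters (distance between consecutive
#'   opposite-foot heel strikes along the path).
#' @param cadence Steps per minute.
#' @param stance_fraction Fraction of the stride spent in stance, in
#'   \[0.4, 0.8\].
#' @param direction_deg Path angle in degrees away from the straight
#'   (camera-perpendicular) direction; 0 = straight.
#' @param n_steps Number of heel strikes in the recording (>= 4).
#' @param subject_height Stature in meters; segment lengths scale with it.
#' @param tap_count,tap_period Number and spacing (s) of the wrist-to-hip
#'   synchronization taps performed while standing, before walking.
#' @param seed Integer seed controlling every random draw downstream.
#'
#' @return List of class `gait_config`.
#' @export
gait_config <- function(step_length = 0.60, cadence = 100,
                        stance_fraction = 0.60, direction_deg = 0,
                        n_steps = 5, subject_height = 1.78,
                        tap_count = 3, tap_period = 1.0, seed = 1L) {
  if (step_length <= 0) stop("step_length must be positive")
  if (stance_fraction < 0.4 || stance_fraction > 0.8)
    stop("stance_fraction must lie in [0.4, 0.8]")
  if (n_steps < 4) stop("need at least 4 steps")
  structure(list(step_length = step_length, cadence = cadence,
                 stance_fraction = stance_fraction,
                 direction_deg = direction_deg, n_steps = n_steps,
                 subject_height = subject_height, tap_count = tap_count,
                 tap_period = tap_period, seed = as.integer(seed)),
            class = "gait_config")
}

#' Scene configuration: cameras, noise and timing
#'
#' @param baseline Camera separation in meters (1.0 or 1.8 in the reference
#'   design).
#' @param camera_height Height of the camera bar above ground (m).
#' @param resolution_mode `"HR"` (1312 x 736) or `"LR"` (640 x 480); both
#'   are scalings of a native 1920 x 1080 sensor, modeled by scaling the
#'   intrinsics.
#' @param pixel_noise_sd Keypoint localization noise (px, per mode's pixel
#'   units) — the same pixel jitter subtends a larger angle at LR, which is
#'   how resolution degrades accuracy here. The jitter is temporally
#'   correlated (AR(1), `noise_rho`), as pose-estimator output drifts
#'   smoothly rather than flickering frame to frame.
#' @param noise_rho Frame-to-frame correlation of the keypoint noise.
#' @param dropout_prob Probability a joint is dropped (confidence 0).
#' @param occlusion_extra_noise Extra jitter (px) on far-side joints when
#'   walking diagonally.
#' @param joint_offset_sd Per-recording constant 3D displacement of each
#'   markerless joint center (m): the pose estimator's skeletal model does
#'   not coincide with marker-derived joint centers.
#' @param occlusion_offset_sd Extra constant displacement (m) of far-side
#'   joints in diagonal walks — occluded landmarks are estimated, not
#'   observed, which biases rather than merely scatters them.
#' @param lag_frames Delay of the markerless streams relative to the
#'   reference, in frames at 30 Hz.
#' @param ref_noise_sd Isotropic noise of the reference system (m);
#'   default 0.2 mm.
#'
#' @return List of class `scene_config`.
#' @export
scene_config <- function(baseline = 1.8, camera_height = 2.3,
                         resolution_mode = c("HR", "LR"),
                         pixel_noise_sd = 0.5, dropout_prob = 0.02,
                         occlusion_extra_noise = 1.0, lag_frames = 10,
                         noise_rho = 0.9, joint_offset_sd = 0.012,
                         occlusion_offset_sd = 0.025, ref_noise_sd = 2e-4) {
  resolution_mode <- match.arg(resolution_mode)
  if (baseline <= 0) stop("baseline must be positive")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0,1]")
  if (noise_rho < 0 || noise_rho >= 1) stop("noise_rho must be in [0,1)")
  structure(list(baseline = baseline, camera_height = camera_height,
                 resolution_mode = resolution_mode,
                 pixel_noise_sd = pixel_noise_sd,
                 dropout_prob = dropout_prob,
                 occlusion_extra_noise = occlusion_extra_noise,
                 lag_frames = as.integer(lag_frames),
                 noise_rho = noise_rho,
                 joint_offset_sd = joint_offset_sd,
                 occlusion_offset_sd = occlusion_offset_sd,
                 ref_noise_sd = ref_noise_sd),
            class = "scene_config")
}

# Anthropometric segment scaling (fractions of stature).
body_dims <- function(H) {
  list(hip_h = 0.53 * H, trunk = 0.30 * H, ankle_h = 0.08,
       upper_arm = 0.186 * H, forearm = 0.146 * H,
       hip_half_width = 0.10, swing_lift = 0.05)
}

# Event schedule of a walk. Heel strike k (k = 1..n_steps) occurs at
# t = T0 + swing_time + (k-1) * step_time, at path distance k * L,
# alternating feet starting with the right.
gait_schedule <- function(cfg) {
  step_time <- 60 / cfg$cadence
  stride_time <- 2 * step_time
  swing_time <- (1 - cfg$stance_fraction) * stride_time
  T0 <- 0.5 + cfg$tap_count * cfg$tap_period
  hs_t <- T0 + swing_time + (seq_len(cfg$n_steps) - 1) * step_time
  hs_s <- seq_len(cfg$n_steps) * cfg$step_length
  hs_foot <- rep(c("right", "left"), length.out = cfg$n_steps)
  # per-foot swing intervals [toe-off, heel-strike] and start/end distances
  # the subject starts from a staggered step-stance (leading foot one step
  # length ahead), so every swing advances a full stride length and the
  # speed pulses are homogeneous from the first step on
  foot_events <- function(foot) {
    k <- which(hs_foot == foot)
    to_t <- hs_t[k] - swing_time
    s_end <- hs_s[k]
    s_start <- c(s_end[1] - 2 * cfg$step_length, s_end[-length(s_end)])
    list(to_t = to_t, hs_t = hs_t[k], s_start = s_start, s_end = s_end)
  }
  # the subject stops and stands at the end of the walkway while the
  # cameras keep rolling, so the recording closes in double-support stance
  tail_len <- 0.6
  list(step_time = step_time, stride_time = stride_time,
       swing_time = swing_time, stance_time = cfg$stance_fraction * stride_time,
       T0 = T0, hs_t = hs_t, hs_s = hs_s, hs_foot = hs_foot,
       right = foot_events("right"), left = foot_events("left"),
       duration = hs_t[cfg$n_steps] + tail_len)
}

# Path distance and lift of one foot's ankle at times t (vectorized).
foot_path <- function(t, ev, lift) {
  s <- numeric(length(t)); z <- numeric(length(t))
  j <- findInterval(t, ev$to_t)
  pre <- j == 0
  s[pre] <- ev$s_start[1]
  act <- !pre
  ji <- pmin(j[act], length(ev$to_t))
  tau <- (t[act] - ev$to_t[ji]) / (ev$hs_t[ji] - ev$to_t[ji])
  in_swing <- tau < 1
  tau_c <- pmin(tau, 1)
  prog <- tau_c - sin(2 * pi * tau_c) / (2 * pi)
  s[act] <- ev$s_start[ji] + (ev$s_end[ji] - ev$s_start[ji]) * prog
  z[act] <- ifelse(in_swing, lift * sin(pi * tau_c), 0)
  list(s = s, z = z)
}

# Full-body pose at arbitrary times. Returns length(t) x 18 x 3 array in
# the lab frame (origin mid-camera at ground, x toward the subject's start,
# z up). Deterministic: the kinematics carry no randomness.
gait_pose <- function(cfg, t) {
  sc <- gait_schedule(cfg)
  bd <- body_dims(cfg$subject_height)
  t <- pmin(pmax(t, 0), sc$duration)
  nt <- length(t)
  L <- cfg$step_length
  th <- cfg$direction_deg * pi / 180
  start <- c(6.0, 0)
  dirv <- c(-cos(th), -sin(th))      # toward the cameras
  latv <- c(-dirv[2], dirv[1])       # left of travel
  place <- function(s, y_local, z) {
    cbind(start[1] + dirv[1] * s + latv[1] * y_local,
          start[2] + dirv[2] * s + latv[2] * y_local,
          z)
  }
  xyz <- array(NA_real_, c(nt, 18, 3))
  jidx <- stats::setNames(seq_len(18), coco18_joints())
  # ankles travel on the path line (no lateral offset), so the step length
  # read from heel-strike positions equals the configured value exactly
  ankR <- foot_path(t, sc$right, bd$swing_lift)
  ankL <- foot_path(t, sc$left, bd$swing_lift)
  xyz[, jidx["RAnkle"], ] <- place(ankR$s, 0, bd$ankle_h + ankR$z)
  xyz[, jidx["LAnkle"], ] <- place(ankL$s, 0, bd$ankle_h + ankL$z)
  # pelvis: mean-speed advance during the walk, frozen outside it
  tw <- pmin(pmax(t - sc$T0, 0), sc$hs_t[length(sc$hs_t)] - sc$T0)
  s_p <- tw * L / sc$step_time
  phase <- 2 * pi * tw / sc$stride_time
  z_p <- bd$hip_h + 0.02 * sin(phase)
  hipR <- place(s_p, -bd$hip_half_width, z_p)
  hipL <- place(s_p, +bd$hip_half_width, z_p)
  xyz[, jidx["RHip"], ] <- hipR
  xyz[, jidx["LHip"], ] <- hipL
  # knees: interpolation hip -> ankle, with a forward bias peaking mid-swing
  knee_of <- function(hip, ank, ft) {
    k <- hip + 0.55 * (ank - hip)
    tau <- swing_tau(t, ft)
    fwd <- 0.03 * sin(pi * pmin(pmax(tau, 0), 1))
    fwd[is.na(fwd)] <- 0
    k[, 1] <- k[, 1] + dirv[1] * fwd
    k[, 2] <- k[, 2] + dirv[2] * fwd
    k
  }
  xyz[, jidx["RKnee"], ] <- knee_of(hipR, xyz[, jidx["RAnkle"], ], sc$right)
  xyz[, jidx["LKnee"], ] <- knee_of(hipL, xyz[, jidx["LAnkle"], ], sc$left)
  # trunk and head
  shR <- hipR; shR[, 3] <- hipR[, 3] + bd$trunk
  shL <- hipL; shL[, 3] <- hipL[, 3] + bd$trunk
  xyz[, jidx["RShoulder"], ] <- shR
  xyz[, jidx["LShoulder"], ] <- shL
  neck <- (shR + shL) / 2
  xyz[, jidx["Neck"], ] <- neck
  nose <- neck; nose[, 3] <- nose[, 3] + 0.13
  nose[, 1] <- nose[, 1] + dirv[1] * 0.03
  nose[, 2] <- nose[, 2] + dirv[2] * 0.03
  xyz[, jidx["Nose"], ] <- nose
  for (side in c("R", "L")) {
    sgn <- if (side == "R") -1 else 1
    eye <- nose
    eye[, 1] <- eye[, 1] + latv[1] * sgn * 0.035
    eye[, 2] <- eye[, 2] + latv[2] * sgn * 0.035
    eye[, 3] <- eye[, 3] + 0.02
    xyz[, jidx[paste0(side, "Eye")], ] <- eye
    ear <- neck
    ear[, 1] <- ear[, 1] + latv[1] * sgn * 0.07
    ear[, 2] <- ear[, 2] + latv[2] * sgn * 0.07
    ear[, 3] <- ear[, 3] + 0.11
    xyz[, jidx[paste0(side, "Ear")], ] <- ear
  }
  # arms: anti-phase pendular swing about the shoulders during the walk;
  # hanging during the prologue, with the right wrist performing the taps
  walk_on <- t >= sc$T0
  armR <- arm_chain(shR, phase, 0, bd, dirv, walk_on)
  armL <- arm_chain(shL, phase, pi, bd, dirv, walk_on)
  xyz[, jidx["RElbow"], ] <- armR$elbow
  xyz[, jidx["RWrist"], ] <- armR$wrist
  xyz[, jidx["LElbow"], ] <- armL$elbow
  xyz[, jidx["LWrist"], ] <- armL$wrist
  # tap prologue: right wrist dips to touch the right hip
  tapw <- tap_weight(t, cfg)
  if (any(tapw > 0)) {
    w <- xyz[, jidx["RWrist"], ]
    tgt <- hipR
    for (d in 1:3) w[, d] <- (1 - tapw) * w[, d] + tapw * tgt[, d]
    xyz[, jidx["RWrist"], ] <- w
  }
  dimnames(xyz) <- list(NULL, coco18_joints(), c("x", "y", "z"))
  xyz
}

# Swing-phase fraction (NA when not in swing) of one foot at times t.
swing_tau <- function(t, ev) {
  j <- findInterval(t, ev$to_t)
  tau <- rep(NA_real_, length(t))
  act <- j > 0
  ji <- pmin(j[act], length(ev$to_t))
  ta <- (t[act] - ev$to_t[ji]) / (ev$hs_t[ji] - ev$to_t[ji])
  ta[ta >= 1] <- NA_real_
  tau[act] <- ta
  tau
}

# Pendular arm: elbow and wrist hanging from the shoulder with a slight
# forward rest flexion (so the wrist sits clear of the hip and the tap
# gesture has usable amplitude), swung by +/- 20 degrees at stride
# frequency while walking.
arm_chain <- function(shoulder, phase, phi, bd, dirv, walk_on) {
  rest <- 12 * pi / 180
  ang <- rest + ifelse(walk_on, 20 * pi / 180 * sin(phase + phi), 0)
  dx <- sin(ang); dz <- -cos(ang)
  elbow <- shoulder
  elbow[, 1] <- elbow[, 1] + dirv[1] * bd$upper_arm * dx
  elbow[, 2] <- elbow[, 2] + dirv[2] * bd$upper_arm * dx
  elbow[, 3] <- elbow[, 3] + bd$upper_arm * dz
  ang2 <- ang + 0.35   # elbow bend carries the wrist further forward
  wrist <- elbow
  wrist[, 1] <- wrist[, 1] + dirv[1] * bd$forearm * sin(ang2)
  wrist[, 2] <- wrist[, 2] + dirv[2] * bd$forearm * sin(ang2)
  wrist[, 3] <- wrist[, 3] - bd$forearm * cos(ang2)
  list(elbow = elbow, wrist = wrist)
}

# Smooth 0 -> 1 -> 0 weight pulling the right wrist onto the right hip at
# each tap instant.
tap_weight <- function(t, cfg) {
  w <- numeric(length(t))
  if (cfg$tap_count < 1) return(w)
  dur <- 0.5 * cfg$tap_period
  starts <- 0.2 + (seq_len(cfg$tap_count) - 1) * cfg$tap_period
  for (s in starts) {
    inside <- t >= s & t <= s + dur
    w[inside] <- pmax(w[inside], sin(pi * (t[inside] - s) / dur)^2)
  }
  w
}

#' Tap instants of the synchronization prologue
#'
#' Times (s) at which the right wrist touches the right hip.
#'
#' @param cfg A `gait_config`.
#' @return Numeric vector of tap center times.
#' @export
tap_times <- function(cfg) {
  0.2 + (seq_len(cfg$tap_count) - 1) * cfg$tap_period + 0.25 * cfg$tap_period
}

#' Simulate a walking recording with known ground truth
#'
#' Deterministic kinematic avatar: stationary stance ankle; swing advancing
#' along the path with a smooth cycloidal profile and a sinusoidal lift;
#' pelvis advancing at the mean gait speed with a small vertical
#' oscillation; arms in anti-phase pendular swing; a standing prologue with
#' the configured wrist-to-hip taps. The returned object carries the true
#' event times and spatio-temporal parameters.
#'
#' @param cfg A `gait_config`.
#'
#' @return List of class `gait_recording`: `config`, `schedule`,
#'   `duration` (s), `gt100` (lab-frame `skeleton3d` at 100 Hz, noise
#'   free), `events` (per-foot heel-strike and toe-off times), and
#'   `true_steps` (data frame of true per-step parameters).
#' @export
simulate_walk <- function(cfg) {
  sc <- gait_schedule(cfg)
  t100 <- seq(0, sc$duration, by = 0.01)
  xyz <- gait_pose(cfg, t100)
  gt100 <- skeleton3d(xyz, frame_rate = 100, frame_ref = "lab",
                      system_id = "ground_truth")
  events <- list(
    right = list(heel_strikes = sc$right$hs_t, toe_offs = sc$right$to_t),
    left = list(heel_strikes = sc$left$hs_t, toe_offs = sc$left$to_t))
  true_steps <- data.frame(
    foot = sc$hs_foot,
    heel_strike_time_s = sc$hs_t,
    step_length_m = cfg$step_length,
    stance_time_s = sc$stance_time,
    swing_time_s = sc$swing_time,
    stride_time_s = sc$stride_time)
  structure(list(config = cfg, schedule = sc, duration = sc$duration,
                 gt100 = gt100, events = events, true_steps = true_steps),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording %d steps, %.2f s, step length %.2f m, cadence %g steps/min>\n",
              x$config$n_steps, x$duration, x$config$step_length,
              x$config$cadence))
  invisible(x)
}

#' Render the marker-based reference stream
#'
#' Samples the ground truth at 100 Hz and adds isotropic Gaussian noise of
#' the reference system's magnitude (0.2 mm by default).
#'
#' @param gt A `gait_recording`.
#' @param scene A `scene_config`.
#' @param seed Seed for the noise draw; defaults to a fixed offset of the
#'   recording's seed.
#'
#' @return A lab-frame `skeleton3d` at 100 Hz, `system_id = "reference"`.
#' @export
render_reference <- function(gt, scene, seed = gt$config$seed + 1000L) {
  xyz <- gt$gt100$xyz
  if (scene$ref_noise_sd > 0) {
    set.seed(seed)
    xyz <- xyz + stats::rnorm(length(xyz), 0, scene$ref_noise_sd)
  }
  skeleton3d(xyz, frame_rate = 100, frame_ref = "lab",
             system_id = "reference")
}

# Intrinsics of one webcam in the given resolution mode. Both modes scale a
# native 1920 x 1080 sensor (f = 1200 px); the rescale acts on the
# intrinsics, never on images.
mode_intrinsics <- function(mode) {
  native_w <- 1920; native_h <- 1080; native_f <- 1200
  res <- switch(mode, HR = c(1312, 736), LR = c(640, 480))
  sx <- res[1] / native_w; sy <- res[2] / native_h
  camera_intrinsics(fx = native_f * sx, fy = native_f * sy,
                    cx = res[1] / 2, cy = res[2] / 2,
                    width = res[1], height = res[2],
                    k1 = -0.04, k2 = 0.01, p1 = 2e-4, p2 = -1e-4)
}

# Look-at rotation: world -> camera (x right, y down, z forward).
look_at <- function(center, target, up = c(0, 0, 1)) {
  z <- target - center; z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rbind(x, y, z)
}

# Build the two-camera rig for a recording: cameras on a bar of length
# `baseline` at `camera_height`, both aimed at the mid-path point (which
# fixes the pitch).
build_rig <- function(gt, scene) {
  cfg <- gt$config
  th <- cfg$direction_deg * pi / 180
  total_s <- cfg$n_steps * cfg$step_length
  mid <- c(6.0 - cos(th) * total_s / 2, -sin(th) * total_s / 2, 1.0)
  CA <- c(0, -scene$baseline / 2, scene$camera_height)
  CB <- c(0, +scene$baseline / 2, scene$camera_height)
  RA <- look_at(CA, mid); RB <- look_at(CB, mid)
  cam <- mode_intrinsics(scene$resolution_mode)
  rig <- stereo_rig(cam, cam, RB %*% t(RA), as.numeric(RB %*% (CA - CB)))
  list(rig = rig, RA = RA, CA = CA, RB = RB, CB = CB)
}

#' Render the two markerless camera streams
#'
#' Samples the ground truth at 30 Hz, delayed by the configured
#' inter-system lag, projects every joint through both cameras of the rig
#' (with lens distortion), then applies keypoint noise, far-side occlusion
#' noise on diagonal paths, and random dropout. Kept joints receive
#' confidences drawn from U(0.4, 1).
#'
#' @param gt A `gait_recording`.
#' @param scene A `scene_config`.
#' @param seed Seed for all noise draws; defaults to a fixed offset of the
#'   recording's seed.
#'
#' @return List: `seriesA`, `seriesB` (`keypoint_series` at 30 Hz), `rig`
#'   (`stereo_rig`), `poses` (the camera geometry used).
#' @export
render_cameras <- function(gt, scene, seed = gt$config$seed + 2000L) {
  geo <- build_rig(gt, scene)
  cfg <- gt$config
  # record long enough that the delayed content still covers the whole walk
  n30 <- floor(gt$duration * 30) + 1 + max(0, scene$lag_frames)
  t30 <- (seq_len(n30) - 1) / 30
  content_t <- t30 - scene$lag_frames / 30
  xyz <- gait_pose(cfg, content_t)       # clamps to [0, duration]
  far_side <- if (cfg$direction_deg != 0)
    grep("^R", coco18_joints()) else integer(0)
  set.seed(seed)
  # systematic landmark-placement error of the pose estimator: a constant
  # 3D displacement per joint, larger on occluded (far-side) joints
  off_sd <- rep(scene$joint_offset_sd, 18)
  if (length(far_side))
    off_sd[far_side] <- sqrt(scene$joint_offset_sd^2 +
                             scene$occlusion_offset_sd^2)
  offsets <- matrix(stats::rnorm(18 * 3), 18, 3) * off_sd
  xyz <- xyz + rep(offsets, each = n30)
  render_one <- function(Rw, C, cam, id) {
    u <- matrix(NA_real_, n30, 18); v <- matrix(NA_real_, n30, 18)
    conf <- matrix(0, n30, 18)
    flat <- matrix(xyz, ncol = 3)
    pc <- sweep(flat, 2, C) %*% t(Rw)
    behind <- pc[, 3] <= 0
    pc[behind, 3] <- NA
    ok <- !behind
    px <- matrix(NA_real_, nrow(pc), 2)
    if (any(ok)) px[ok, ] <- project_points(pc[ok, , drop = FALSE], cam)
    pu <- matrix(px[, 1], n30, 18); pv <- matrix(px[, 2], n30, 18)
    sd_px <- matrix(scene$pixel_noise_sd, n30, 18)
    if (length(far_side)) sd_px[, far_side] <-
      sqrt(scene$pixel_noise_sd^2 + scene$occlusion_extra_noise^2)
    # AR(1) jitter with unit marginal variance per joint coordinate
    ar1 <- function() {
      e <- matrix(stats::rnorm(n30 * 18), n30, 18)
      if (scene$noise_rho > 0 && n30 > 1) {
        for (i in 2:n30)
          e[i, ] <- scene$noise_rho * e[i - 1, ] +
            sqrt(1 - scene$noise_rho^2) * e[i, ]
      }
      e
    }
    pu <- pu + ar1() * sd_px
    pv <- pv + ar1() * sd_px
    inside <- !is.na(pu) & !is.na(pv) &
      pu >= 0 & pu <= cam$width & pv >= 0 & pv <= cam$height
    drop <- matrix(stats::runif(n30 * 18) < scene$dropout_prob, n30, 18)
    keep <- inside & !drop
    conf[keep] <- stats::runif(sum(keep), 0.4, 1.0)
    u[keep] <- pu[keep]; v[keep] <- pv[keep]
    keypoint_series(u, v, conf, frame_rate = 30, camera_id = id,
                    resolution = c(cam$width, cam$height))
  }
  sA <- render_one(geo$RA, geo$CA, geo$rig$camA, "camA")
  sB <- render_one(geo$RB, geo$CB, geo$rig$camB, "camB")
  # the subject must stay visible to at least one camera
  neck <- match("Neck", coco18_joints())
  lost <- which(sA$conf[, neck] == 0 & sB$conf[, neck] == 0)
  if (length(lost) > 0.5 * n30)
    stop(sprintf("subject leaves both camera frusta at %d/%d frames (e.g. frames %s)",
                 length(lost), n30,
                 paste(utils::head(lost, 5), collapse = ", ")))
  list(seriesA = sA, seriesB = sB, rig = geo$rig, poses = geo)
}

#' Full factorial batch of simulated recordings
#'
#' Enumerates the 2 x 2 x 2 design (gait direction straight/diagonal,
#' camera baseline 1.0/1.8 m, resolution LR/HR) with the given number of
#' replicates per cell and subjects (statures 1.73 m and 1.82 m), assigning
#' each run a distinct seed derived from `seed`. The default design yields
#' 8 x 3 x 2 = 48 recordings.
#'
#' @param replicates Replicates per cell and subject (default 3).
#' @param subjects Number of subjects, at most 2 (default 2).
#' @param seed Master seed.
#' @param diagonal_deg Path angle used for the diagonal condition
#'   (default 20).
#' @param scene_defaults A `scene_config` supplying the noise model shared
#'   by all runs.
#'
#' @return Data frame manifest, one row per recording: factor levels and
#'   their -1/+1 codes (`x1` direction, `x2` distance, `x3` resolution),
#'   subject stature, replicate and per-run seed.
#' @export
simulate_batch <- function(replicates = 3, subjects = 2, seed = 1L,
                           diagonal_deg = 20,
                           scene_defaults = scene_config()) {
  stopifnot(replicates >= 1, subjects >= 1, subjects <= 2)
  heights <- c(1.73, 1.82)[seq_len(subjects)]
  grid <- expand.grid(direction = c("straight", "diagonal"),
                      baseline = c(1.0, 1.8),
                      resolution = c("LR", "HR"),
                      subject = seq_len(subjects),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  grid$subject_height <- heights[grid$subject]
  grid$direction_deg <- ifelse(grid$direction == "diagonal", diagonal_deg, 0)
  grid$x1 <- ifelse(grid$direction == "diagonal", 1, -1)
  grid$x2 <- ifelse(grid$baseline == 1.8, 1, -1)
  grid$x3 <- ifelse(grid$resolution == "HR", 1, -1)
  grid$run <- seq_len(nrow(grid))
  grid$seed <- as.integer(seed) * 1000L + grid$run
  grid$pixel_noise_sd <- scene_defaults$pixel_noise_sd
  grid$dropout_prob <- scene_defaults$dropout_prob
  grid$occlusion_extra_noise <- scene_defaults$occlusion_extra_noise
  grid$lag_frames <- scene_defaults$lag_frames
  grid$noise_rho <- scene_defaults$noise_rho
  grid$joint_offset_sd <- scene_defaults$joint_offset_sd
  grid$occlusion_offset_sd <- scene_defaults$occlusion_offset_sd
  grid$ref_noise_sd <- scene_defaults$ref_noise_sd
  grid[, c("run", "direction", "baseline", "resolution", "subject",
           "replicate", "subject_height", "direction_deg", "x1", "x2", "x3",
           "seed", "pixel_noise_sd", "dropout_prob", "occlusion_extra_noise",
           "lag_frames", "noise_rho", "joint_offset_sd", "occlusion_offset_sd",
           "ref_noise_sd")]
}

#' Configurations for one manifest row
#'
#' Rebuilds the `gait_config` and `scene_config` of a batch run.
#'
#' @param row One row of the manifest from [simulate_batch()].
#' @param ... Overrides passed to [gait_config()] (e.g. `n_steps`).
#' @return List with `gait` and `scene`.
#' @export
manifest_configs <- function(row, ...) {
  list(gait = gait_config(direction_deg = row$direction_deg,
                          subject_height = row$subject_height,
                          seed = row$seed, ...),
       scene = scene_config(baseline = row$baseline,
                            resolution_mode = row$resolution,
                            pixel_noise_sd = row$pixel_noise_sd,
                            dropout_prob = row$dropout_prob,
                            occlusion_extra_noise = row$occlusion_extra_noise,
                            lag_frames = row$lag_frames,
                            noise_rho = row$noise_rho,
                            joint_offset_sd = row$joint_offset_sd,
                            occlusion_offset_sd = row$occlusion_offset_sd,
                            ref_noise_sd = row$ref_noise_sd))
}

#' Write one simulated recording to disk in the pipeline's file formats
#'
#' Emits the two OpenPose JSON directories, the reference trajectory CSV,
#' the calibration JSON and a ground-truth JSON (events and true
#' parameters).
#'
#' @param gt A `gait_recording`.
#' @param scene A `scene_config`.
#' @param dir Output directory.
#' @return Invisibly, the list of paths written.
#' @export
write_recording <- function(gt, scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cams <- render_cameras(gt, scene)
  ref <- render_reference(gt, scene)
  pA <- file.path(dir, "camA"); pB <- file.path(dir, "camB")
  write_openpose_dir(cams$seriesA, pA)
  write_openpose_dir(cams$seriesB, pB)
  pref <- file.path(dir, "reference.csv")
  write_trajectory_table(ref, pref)
  pcal <- file.path(dir, "calibration.json")
  write_calibration(cams$rig, pcal)
  ptruth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(events = gt$events, true_steps = gt$true_steps,
                            duration = gt$duration,
                            config = unclass(gt$config),
                            lag_frames = scene$lag_frames),
                       ptruth, auto_unbox = TRUE, digits = NA)
  invisible(list(camA = pA, camB = pB, reference = pref,
                 calibration = pcal, ground_truth = ptruth))
}
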