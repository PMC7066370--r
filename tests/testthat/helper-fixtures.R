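# Shared fixtures: small camera rigs and skeleton series built in code.

# A forward-looking stereo rig with parallel cameras `baseline` m apart.
make_rig <- function(baseline = 1.8, distortion = FALSE) {
  d <- if (distortion) list(k1 = -0.04, k2 = 0.01, p1 = 2e-4, p2 = -1e-4)
       else list(k1 = 0, k2 = 0, p1 = 0, p2 = 0)
  cam <- camera_intrinsics(fx = 820, fy = 818, cx = 656, cy = 368,
                           width = 1312, height = 736,
                           k1 = d$k1, k2 = d$k2, p1 = d$p1, p2 = d$p2)
  stereo_rig(cam, cam, diag(3), c(-baseline, 0, 0))
}

# Project lab... camera-frame 3D points through both cameras of a rig.
project_pair <- function(X, rig) {
  X <- matrix(X, ncol = 3)
  XB <- t(rig$R %*% t(X) + rig$t)
  list(A = project_points(X, rig$camA), B = project_points(XB, rig$camB))
}

# A skeleton series with all 18 joints at given per-frame offsets of a
# template pose (upright standing figure).
standing_pose <- function() {
  xyz <- matrix(0, 18, 3, dimnames = list(coco18_joints(), c("x", "y", "z")))
  xyz[, "z"] <- c(1.65, 1.55, 1.48, 1.2, 0.95, 1.48, 1.2, 0.95,
                  0.95, 0.5, 0.08, 0.95, 0.5, 0.08, 1.67, 1.67, 1.6, 1.6)
  xyz[, "y"] <- c(0, 0, -0.18, -0.2, -0.22, 0.18, 0.2, 0.22,
                  -0.1, -0.1, -0.1, 0.1, 0.1, 0.1, -0.03, 0.03, -0.07, 0.07)
  xyz
}

make_skeleton <- function(n = 30, frame_rate = 30, drift = c(0.01, 0, 0),
                          frame_ref = "lab", system_id = "test") {
  pose <- standing_pose()
  xyz <- array(NA_real_, c(n, 18, 3))
  for (i in seq_len(n))
    xyz[i, , ] <- pose + rep((i - 1) * drift, each = 18)
  skeleton3d(xyz, frame_rate = frame_rate, frame_ref = frame_ref,
             system_id = system_id)
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Noise-free rendered recording at the default study conditions.
noise_free_scene <- function(lag_frames = 0) {
  scene_config(pixel_noise_sd = 0, dropout_prob = 0,
               occlusion_extra_noise = 0, joint_offset_sd = 0,
               occlusion_offset_sd = 0, ref_noise_sd = 0,
               lag_frames = lag_frames)
}
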