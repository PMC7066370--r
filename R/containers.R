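#' COCO-18 keypoint names
#'
#' Joint names of the 18-keypoint body model, in slot order (slot 1 = index 0
#' of the on-disk format). All skeleton containers in this package use this
#' ordering.
#'
#' @return Character vector of length 18.
#' @export
coco18_joints <- function() {
  c("Nose", "Neck", "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist", "RHip", "RKnee",
    "RAnkle", "LHip", "LKnee", "LAnkle", "REye", "LEye",
    "REar", "LEar")
}

#' Evaluation node names
#'
#' The 13 skeletal nodes used for trajectory-error evaluation: the neck
#' (sternum surrogate), shoulders, elbows, wrists, hips, knees and ankles.
#' Face keypoints are excluded: a marker-based reference has no reliable
#' counterpart for them.
#'
#' @return Character vector of length 13.
#' @export
eval_nodes <- function() {
  coco18_joints()[2:14]
}

#' Camera intrinsics (pinhole + Brown-Conrady distortion)
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels, inside the image.
#' @param k1,k2,k3 Radial distortion coefficients.
#' @param p1,p2 Tangential distortion coefficients.
#' @param width,height Image size in pixels.
#'
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height,
                              k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  if (!is.finite(fx) || !is.finite(fy) || fx <= 0 || fy <= 0)
    stop("focal lengths must be positive and finite")
  if (cx < 0 || cx > width || cy < 0 || cy > height)
    stop("principal point must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics %dx%d f=(%.1f, %.1f) c=(%.1f, %.1f)>\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

# Nearest rotation matrix (polar decomposition via SVD), proper (det +1).
nearest_rotation <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

orthonormality_error <- function(R) {
  max(abs(crossprod(R) - diag(3)))
}

#' Two-camera rig
#'
#' Two camera models plus their relative rigid pose: `R`, `t` map camera-A
#' coordinates into camera-B coordinates, `X_B = R %*% X_A + t`.
#'
#' @param camA,camB `camera_intrinsics` objects.
#' @param R 3x3 rotation (camera A to camera B).
#' @param t Length-3 translation in meters.
#' @param tol Orthonormality tolerance beyond which `R` is rejected rather
#'   than re-orthonormalized.
#'
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(camA, camB, R, t, tol = 1e-6) {
  stopifnot(inherits(camA, "camera_intrinsics"),
            inherits(camB, "camera_intrinsics"))
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop("R must be 3x3")
  if (det(R) <= 0) stop("R is not a proper rotation (det(R) <= 0)")
  err <- orthonormality_error(R)
  if (err > tol)
    stop(sprintf("R is %.2e off orthonormal (tolerance %.0e)", err, tol))
  if (err > 0) R <- nearest_rotation(R)
  t <- as.numeric(t)
  if (length(t) != 3) stop("t must have length 3")
  rig <- structure(list(camA = camA, camB = camB, R = R, t = t),
                   class = "stereo_rig")
  if (rig_baseline(rig) <= 0) stop("degenerate rig: zero baseline")
  rig
}

#' Baseline of a stereo rig
#'
#' Distance between the two optical centers, in meters.
#'
#' @param rig A `stereo_rig`.
#' @return Numeric scalar (m).
#' @export
rig_baseline <- function(rig) {
  # camera B center in A coordinates is -R^T t
  sqrt(sum((crossprod(rig$R, -rig$t))^2))
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig baseline=%.3f m>\n", rig_baseline(x)))
  invisible(x)
}

#' Keypoint series from one camera
#'
#' A 2D keypoint stream: per-frame pixel coordinates and confidences for the
#' 18 COCO joints. A confidence of zero marks a missing joint.
#'
#' @param u,v Numeric matrices, frames x 18, pixel coordinates.
#' @param conf Numeric matrix, frames x 18, confidences in \[0, 1\].
#' @param frame_rate Frames per second (default 30).
#' @param camera_id Label for the source camera.
#' @param resolution Integer pair (width, height) in pixels.
#'
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(u, v, conf, frame_rate = 30,
                            camera_id = "cam", resolution = c(NA, NA)) {
  u <- as.matrix(u); v <- as.matrix(v); conf <- as.matrix(conf)
  stopifnot(ncol(u) == 18, all(dim(u) == dim(v)), all(dim(u) == dim(conf)))
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]")
  colnames(u) <- colnames(v) <- colnames(conf) <- coco18_joints()
  structure(list(u = u, v = v, conf = conf,
                 frame_rate = frame_rate, camera_id = camera_id,
                 resolution = resolution),
            class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series '%s' %d frames @ %g Hz, %.1f%% joints missing>\n",
              x$camera_id, nrow(x$u), x$frame_rate,
              100 * mean(x$conf == 0)))
  invisible(x)
}

n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.keypoint_series <- function(x) nrow(x$u)
#' @export
n_frames.skeleton3d <- function(x) dim(x$xyz)[1]

#' Time-stamped 3D skeleton series
#'
#' Joint-center trajectories in meters, with a per-joint validity mask and an
#' explicit reference-frame label. Both the triangulated markerless stream
#' and the marker-based reference table use this container.
#'
#' @param xyz Numeric array frames x joints x 3 (meters).
#' @param valid Logical matrix frames x joints; invalid positions carry no
#'   usable coordinates.
#' @param frame_rate Frames per second.
#' @param frame_ref Reference-frame label (e.g. `"cameraA"`, `"lab"`).
#' @param joints Joint names; defaults to the COCO-18 set.
#' @param system_id Label of the originating measurement system.
#' @param t0 Time of the first frame in seconds (default 0).
#'
#' @return An object of class `skeleton3d`.
#' @export
skeleton3d <- function(xyz, valid = NULL, frame_rate = 30, frame_ref = "lab",
                       joints = coco18_joints(), system_id = "unknown",
                       t0 = 0) {
  xyz <- unname(xyz)
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3,
            dim(xyz)[2] == length(joints))
  if (is.null(valid)) valid <- !is.na(xyz[, , 1, drop = FALSE])[, , 1]
  valid <- matrix(as.logical(valid), nrow = dim(xyz)[1])
  if (any(!is.finite(xyz[rep(valid, 3)])))
    stop("valid positions must be finite")
  dimnames(xyz) <- list(NULL, joints, c("x", "y", "z"))
  colnames(valid) <- joints
  structure(list(xyz = xyz, valid = valid, frame_rate = frame_rate,
                 frame_ref = frame_ref, joints = joints,
                 system_id = system_id, t0 = t0),
            class = "skeleton3d")
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d '%s' %d frames x %d joints @ %g Hz, frame '%s', %.1f%% valid>\n",
              x$system_id, dim(x$xyz)[1], length(x$joints), x$frame_rate,
              x$frame_ref, 100 * mean(x$valid)))
  invisible(x)
}

#' Frame timestamps of a skeleton series
#'
#' @param x A `skeleton3d`.
#' @return Numeric vector of times in seconds.
#' @export
skeleton_times <- function(x) {
  x$t0 + (seq_len(dim(x$xyz)[1]) - 1) / x$frame_rate
}

# Extract one joint's trajectory as an n x 3 matrix (NA where invalid).
joint_xyz <- function(series, joint) {
  j <- match(joint, series$joints)
  if (is.na(j)) stop(sprintf("joint '%s' not present in series", joint))
  m <- series$xyz[, j, , drop = FALSE]
  dim(m) <- c(dim(series$xyz)[1], 3)
  m[!series$valid[, j], ] <- NA_real_
  m
}

#' Rigid transform between named frames
#'
#' @param R 3x3 proper rotation.
#' @param t Length-3 translation (m).
#' @param from_frame,to_frame Frame labels.
#'
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, t, from_frame = "A", to_frame = "B") {
  R <- as.matrix(R)
  if (orthonormality_error(R) > 1e-9 || det(R) <= 0)
    stop("R must be a proper rotation (orthonormal, det +1)")
  structure(list(R = R, t = as.numeric(t),
                 from_frame = from_frame, to_frame = to_frame),
            class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' @param T A `rigid_transform`.
#' @return The inverse `rigid_transform` (frames swapped).
#' @export
invert_transform <- function(T) {
  rigid_transform(t(T$R), -crossprod(T$R, T$t),
                  from_frame = T$to_frame, to_frame = T$from_frame)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform '%s' -> '%s': rotation %.2f deg, |t| = %.3f m>\n",
              x$from_frame, x$to_frame, ang, sqrt(sum(x$t^2))))
  invisible(x)
}
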