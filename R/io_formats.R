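# On-disk formats: OpenPose-dialect keypoint JSON directories, trajectory
# CSV tables, calibration JSON, step-record CSV, rigid-transform JSON.

#' Read a directory of OpenPose per-frame JSON files
#'
#' Each file holds `{"people": [{"pose_keypoints_2d": [x0,y0,c0, ...]}]}`
#' with 18 keypoint triplets (the COCO body model). Files are taken in
#' lexicographic order (zero-padded frame numbering). A frame with an empty
#' `people` array becomes an all-missing frame. Files with 25-keypoint
#' (BODY_25) arrays are rejected: this package is fixed to the 18-keypoint
#' model.
#'
#' @param path Directory of per-frame `.json` files.
#' @param person_policy With several detected people, either
#'   `"highest_total_confidence"` (keep the person whose confidences sum
#'   highest; the pipeline assumes a single walking subject) or
#'   `"error_if_multiple"`.
#' @param frame_rate Frames per second of the recording (default 30).
#' @param camera_id Label stored on the returned series.
#' @param resolution Optional (width, height) in pixels.
#'
#' @return A `keypoint_series`.
#' @export
read_openpose_dir <- function(path,
                              person_policy = c("highest_total_confidence",
                                                "error_if_multiple"),
                              frame_rate = 30, camera_id = basename(path),
                              resolution = c(NA, NA)) {
  person_policy <- match.arg(person_policy)
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no JSON frame files found in '%s'", path))
  n <- length(files)
  u <- matrix(NA_real_, n, 18); v <- matrix(NA_real_, n, 18)
  conf <- matrix(0, n, 18)
  for (i in seq_len(n)) {
    doc <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("malformed JSON in '%s': %s",
                                   files[i], conditionMessage(e))))
    people <- doc$people
    if (is.null(people) || length(people) == 0) next   # all-missing frame
    kp_of <- function(p) as.numeric(unlist(p$pose_keypoints_2d))
    if (length(people) > 1) {
      if (person_policy == "error_if_multiple")
        stop(sprintf("multiple people in '%s'", files[i]))
      scores <- vapply(people, function(p) {
        k <- kp_of(p); sum(k[seq(3, length(k), by = 3)])
      }, numeric(1))
      people <- people[which.max(scores)]
    }
    kp <- kp_of(people[[1]])
    if (length(kp) == 75)
      stop(sprintf("'%s' holds a 25-keypoint (BODY_25) skeleton; only the 18-keypoint COCO model is supported",
                   files[i]))
    if (length(kp) != 54)
      stop(sprintf("'%s': expected 54 numbers (18 keypoint triplets), got %d",
                   files[i], length(kp)))
    u[i, ] <- kp[seq(1, 54, by = 3)]
    v[i, ] <- kp[seq(2, 54, by = 3)]
    conf[i, ] <- kp[seq(3, 54, by = 3)]
  }
  u[conf == 0] <- NA_real_
  v[conf == 0] <- NA_real_
  keypoint_series(u, v, conf, frame_rate = frame_rate,
                  camera_id = camera_id, resolution = resolution)
}

#' Write a keypoint series as an OpenPose-dialect JSON directory
#'
#' One file per frame, named `frame_000000000000.json` onward. Missing
#' joints are written as the conventional `(0, 0, 0)` triplet.
#'
#' @param series A `keypoint_series`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_openpose_dir <- function(series, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path))
  n <- n_frames(series)
  files <- file.path(path, sprintf("frame_%012d_keypoints.json", seq_len(n) - 1))
  for (i in seq_len(n)) {
    kp <- numeric(54)
    kp[seq(1, 54, 3)] <- series$u[i, ]
    kp[seq(2, 54, 3)] <- series$v[i, ]
    kp[seq(3, 54, 3)] <- series$conf[i, ]
    kp[is.na(kp)] <- 0   # missing joints: conventional (0, 0, 0) triplet
    doc <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = kp)))
    jsonlite::write_json(doc, files[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(files)
}

#' Read a long-format trajectory table
#'
#' CSV schema: `frame,time_s,joint,x_m,y_m,z_m,valid`. Frames must be
#' non-decreasing; each (frame, joint) pair appears once.
#'
#' @param path CSV file.
#' @param frame_rate Sampling rate in Hz; if `NULL`, inferred from the
#'   `time_s` column.
#' @param system_id Label stored on the returned series.
#' @param frame_ref Reference-frame label (default `"lab"`).
#'
#' @return A `skeleton3d`.
#' @export
read_trajectory_table <- function(path, frame_rate = NULL,
                                  system_id = "reference", frame_ref = "lab") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "joint", "x_m", "y_m", "z_m", "valid")
  if (!all(need %in% names(df)))
    stop(sprintf("trajectory table '%s' missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  frames <- sort(unique(df$frame))
  if (any(diff(frames) <= 0)) stop("non-monotone frame indices")
  joints <- unique(df$joint)
  n <- length(frames)
  if (is.null(frame_rate)) {
    tt <- tapply(df$time_s, df$frame, function(x) x[1])
    frame_rate <- if (n > 1) round(1 / stats::median(diff(as.numeric(tt))), 6) else 100
  }
  xyz <- array(NA_real_, c(n, length(joints), 3))
  valid <- matrix(FALSE, n, length(joints))
  fi <- match(df$frame, frames)
  ji <- match(df$joint, joints)
  ok <- df$valid != 0
  xyz[cbind(fi, ji, 1)] <- ifelse(ok, df$x_m, NA_real_)
  xyz[cbind(fi, ji, 2)] <- ifelse(ok, df$y_m, NA_real_)
  xyz[cbind(fi, ji, 3)] <- ifelse(ok, df$z_m, NA_real_)
  valid[cbind(fi, ji)] <- ok
  t0 <- min(df$time_s)
  skeleton3d(xyz, valid, frame_rate = frame_rate, frame_ref = frame_ref,
             joints = joints, system_id = system_id, t0 = t0)
}

#' Write a skeleton series as a long-format trajectory CSV
#'
#' @param series A `skeleton3d`.
#' @param path Output CSV file.
#' @return Invisibly, `path`.
#' @export
write_trajectory_table <- function(series, path) {
  n <- dim(series$xyz)[1]; J <- length(series$joints)
  tm <- skeleton_times(series)
  df <- data.frame(
    frame = rep(seq_len(n) - 1, each = J),
    time_s = rep(tm, each = J),
    joint = rep(series$joints, n),
    x_m = as.numeric(aperm(series$xyz, c(2, 1, 3))[, , 1]),
    y_m = as.numeric(aperm(series$xyz, c(2, 1, 3))[, , 2]),
    z_m = as.numeric(aperm(series$xyz, c(2, 1, 3))[, , 3]),
    valid = as.integer(t(series$valid)))
  df[df$valid == 0, c("x_m", "y_m", "z_m")] <- 0
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stereo calibration file
#'
#' JSON with fields `cameraA`, `cameraB` (each `fx, fy, cx, cy, k1, k2, k3,
#' p1, p2, width, height`), `R` (3x3 rotation, row-major or nested, mapping
#' camera-A to camera-B coordinates) and `t` (meters). A rotation within
#' 1e-6 of orthonormal is re-orthonormalized; anything worse, or a
#' reflection, is rejected.
#'
#' @param path Calibration JSON (or YAML) file.
#' @return A `stereo_rig`.
#' @export
read_calibration <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML calibration files")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  cam <- function(d) camera_intrinsics(
    fx = d$fx, fy = d$fy, cx = d$cx, cy = d$cy,
    width = d$width, height = d$height,
    k1 = d$k1 %||% 0, k2 = d$k2 %||% 0, k3 = d$k3 %||% 0,
    p1 = d$p1 %||% 0, p2 = d$p2 %||% 0)
  R <- json_matrix3(doc$R)
  stereo_rig(cam(doc$cameraA), cam(doc$cameraB), R, as.numeric(doc$t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 3x3 row-major matrix from parsed JSON: jsonlite may hand back an
# already-simplified matrix (rows preserved) or a list of row vectors.
json_matrix3 <- function(x) {
  if (is.matrix(x)) return(matrix(as.numeric(x), 3, 3))
  matrix(as.numeric(unlist(x)), 3, 3, byrow = TRUE)
}

#' Write a stereo calibration file
#'
#' @param rig A `stereo_rig`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(rig, path) {
  cam <- function(c) c[c("fx", "fy", "cx", "cy", "k1", "k2", "k3",
                         "p1", "p2", "width", "height")]
  doc <- list(cameraA = cam(rig$camA), cameraB = cam(rig$camB),
              R = lapply(1:3, function(i) rig$R[i, ]),
              t = rig$t)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write step-record tables
#'
#' CSV schema: `foot,heel_strike_time_s,step_length_m,stance_time_s,
#' swing_time_s` (plus `complete`).
#'
#' @param path CSV file.
#' @return A data frame of step records.
#' @export
read_step_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("foot", "heel_strike_time_s", "step_length_m",
            "stance_time_s", "swing_time_s")
  if (!all(need %in% names(df)))
    stop(sprintf("step-record table missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' @rdname read_step_records
#' @param steps Data frame of step records (as produced by
#'   [compute_step_parameters()]).
#' @export
write_step_records <- function(steps, path) {
  utils::write.csv(steps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a rigid transform as JSON
#'
#' Serialization used for pipeline checkpointing: rotation row-major,
#' translation in meters, frame labels.
#'
#' @param T A `rigid_transform`.
#' @param path JSON file.
#' @export
write_transform <- function(T, path) {
  doc <- list(R = lapply(1:3, function(i) T$R[i, ]), t = T$t,
              from_frame = T$from_frame, to_frame = T$to_frame)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  doc <- jsonlite::fromJSON(path)
  rigid_transform(json_matrix3(doc$R),
                  as.numeric(doc$t), doc$from_frame, doc$to_frame)
}
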