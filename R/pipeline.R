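# Orchestration of the full measurement chain: triangulation,
# synchronization, lab alignment, filtering, gait events, parameters and
# evaluation — in memory and from files.

# Slice a window of frames out of a skeleton series, keeping timestamps.
skeleton_window <- function(series, from, to) {
  idx <- from:to
  skeleton3d(series$xyz[idx, , , drop = FALSE],
             series$valid[idx, , drop = FALSE],
             frame_rate = series$frame_rate, frame_ref = series$frame_ref,
             joints = series$joints, system_id = series$system_id,
             t0 = series$t0 + (from - 1) / series$frame_rate)
}

# Low-pass filter every joint coordinate of a series, run by run: each
# maximal valid run long enough for the filter is smoothed; shorter runs
# are left as they are.
filter_skeleton <- function(series, fc = 10) {
  xyz <- series$xyz
  min_len <- 3 * (2 + 1) + 1
  for (j in seq_len(dim(xyz)[2])) {
    ok <- series$valid[, j]
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (g in which(r$values & r$lengths >= min_len)) {
      idx <- starts[g]:ends[g]
      for (d in 1:3)
        xyz[idx, j, d] <- butter2_zero_phase(xyz[idx, j, d],
                                             fs = series$frame_rate, fc = fc)
    }
  }
  skeleton3d(xyz, series$valid, frame_rate = series$frame_rate,
             frame_ref = series$frame_ref, joints = series$joints,
             system_id = series$system_id, t0 = series$t0)
}

# Smooth a speed series run by run with the zero-phase moving average.
smooth_speed <- function(speed, window = 24) {
  v <- speed$v
  ok <- speed$valid & !is.na(v)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (g in which(r$values & r$lengths > window)) {
    idx <- starts[g]:ends[g]
    v[idx] <- moving_average_smooth(v[idx], window)
  }
  structure(list(v = v, valid = speed$valid, frame_rate = speed$frame_rate,
                 foot = speed$foot),
            class = "speed_series")
}

# Active gait span: frames where either foot's smoothed speed exceeds 30%
# of the overall maximum. Restricting threshold calibration to this span
# keeps the standing synchronization prologue out of the speed histogram.
gait_span <- function(speedL, speedR) {
  v <- pmax(ifelse(speedL$valid, speedL$v, 0),
            ifelse(speedR$valid, speedR$v, 0), na.rm = TRUE)
  v[is.na(v)] <- 0
  thr <- 0.3 * max(v)
  act <- which(v > thr)
  if (length(act) == 0) stop("no gait activity found in recording")
  c(act[1], act[length(act)])
}

# Gait events and step parameters of one lab-frame skeleton series.
gait_analysis <- function(series, smoother_window = 24) {
  spL <- smooth_speed(ankle_speed(series, "left"), smoother_window)
  spR <- smooth_speed(ankle_speed(series, "right"), smoother_window)
  span <- gait_span(spL, spR)
  calib <- function(sp) {
    w <- sp
    w$v <- sp$v[span[1]:span[2]]
    w$valid <- sp$valid[span[1]:span[2]]
    estimate_thresholds(w)
  }
  thL <- calib(spL); thR <- calib(spR)
  stL <- detect_foot_states(spL, thL)
  stR <- detect_foot_states(spR, thR)
  steps <- compute_step_parameters(stL, stR, series)
  list(steps = steps, states = list(left = stL, right = stR),
       thresholds = list(left = thL, right = thR),
       speeds = list(left = spL, right = spR), span = span)
}

#' Run the full measurement chain on one recording
#'
#' Triangulates the two keypoint streams, fills short dropout gaps,
#' low-pass filters both systems' coordinates (10 Hz zero-lag Butterworth),
#' downsamples the reference to the camera rate, synchronizes the streams
#' through the wrist-to-hip gesture, aligns the markerless series into the
#' laboratory frame (Kabsch), detects gait events on both systems, extracts
#' spatio-temporal parameters and evaluates trajectory and parameter
#' errors against the reference.
#'
#' @param seriesA,seriesB `keypoint_series` from the two cameras.
#' @param rig The `stereo_rig` joining them.
#' @param ref Reference `skeleton3d` (lab frame; any rate >= 30 Hz).
#' @param fc Butterworth cut-off (Hz, default 10).
#' @param smoother_window Speed-smoother width in samples (default 24).
#' @param max_lag Largest synchronization lag searched (frames, default 90).
#' @param keep_series Keep the intermediate skeleton series in the result.
#'
#' @return List of class `gait_report`: `lag_frames`, `lab_transform`,
#'   `node_report`, `steps_op`, `steps_ref`, `matches`, `param_report`,
#'   `bland_altman` (per parameter), `thresholds`, and (optionally)
#'   `series`.
#' @export
run_recording <- function(seriesA, seriesB, rig, ref, fc = 10,
                          smoother_window = 24, max_lag = 90,
                          keep_series = FALSE) {
  op <- triangulate_series(seriesA, seriesB, rig)
  op <- fill_short_gaps(op)
  op <- filter_skeleton(op, fc = fc)
  ref_f <- filter_skeleton(ref, fc = fc)
  ref30 <- if (ref_f$frame_rate > op$frame_rate)
    resample_skeleton(ref_f, op$frame_rate) else ref_f
  # the tap gesture lives below ~3 Hz; smoothing the distance signals
  # before correlating suppresses broadband triangulation noise
  smooth_gesture <- function(g) {
    v <- g$values
    ok <- !is.na(v)
    if (sum(!ok) > 0 && sum(ok) >= 2)
      v[!ok] <- stats::approx(which(ok), v[ok], xout = which(!ok),
                              rule = 2)$y
    g$values <- butter2_zero_phase(v, fs = g$frame_rate, fc = 3)
    g
  }
  lag <- estimate_lag(smooth_gesture(gesture_signal(op)),
                      smooth_gesture(gesture_signal(ref30)),
                      max_lag = max_lag)
  n_op <- dim(op$xyz)[1]; n_ref <- dim(ref30$xyz)[1]
  i1 <- max(1, 1 - lag); i2 <- min(n_op, n_ref - lag)
  if (i2 - i1 < 2 * op$frame_rate)
    stop("less than 2 s of synchronized overlap between the systems")
  op_sync <- skeleton_window(op, i1, i2)
  ref_sync <- skeleton_window(ref30, i1 + lag, i2 + lag)
  op_sync$t0 <- ref_sync$t0   # synchronized pair shares the reference clock
  lab <- build_lab_transform(op_sync, ref_sync)
  op_lab <- apply_transform(op_sync, lab)
  cmp <- align_for_comparison(op_sync, ref_sync)
  nr <- node_rms(cmp$aligned, ref_sync)
  # a noisy recording can defeat the event detector; trajectory metrics
  # survive, step metrics are reported absent with the failure message
  ga <- tryCatch(
    list(op = gait_analysis(op_lab, smoother_window),
         ref = gait_analysis(ref_sync, smoother_window)),
    error = function(e) conditionMessage(e))
  gait_error <- if (is.character(ga)) ga else NULL
  ga_op <- if (is.list(ga)) ga$op else NULL
  ga_ref <- if (is.list(ga)) ga$ref else NULL
  steps <- if (is.null(ga_op)) NULL else
    list(op = ga_op$steps, ref = ga_ref$steps)
  mt <- pe <- ba <- NULL
  if (!is.null(steps)) {
    mt <- match_steps(steps$op, steps$ref)
    pe <- if (!is.null(mt$pairs)) tryCatch(param_errors(mt$pairs),
                                           error = function(e) NULL)
    ba <- if (!is.null(mt$pairs) && nrow(mt$pairs) >= 3)
      lapply(c("step_length_m", "stance_time_s", "swing_time_s"),
             function(p) tryCatch(bland_altman(mt$pairs, p),
                                  error = function(e) NULL))
    if (!is.null(ba)) names(ba) <- c("step_length_m", "stance_time_s",
                                     "swing_time_s")
  }
  out <- list(lag_frames = lag, lab_transform = lab,
              eval_transform = cmp$transform, node_report = nr,
              steps_op = if (is.null(steps)) NULL else steps$op,
              steps_ref = if (is.null(steps)) NULL else steps$ref,
              matches = mt, param_report = pe, bland_altman = ba,
              thresholds = if (is.null(ga_op)) NULL else
                list(op = ga_op$thresholds, ref = ga_ref$thresholds),
              gait_error = gait_error)
  if (keep_series) {
    out$series <- list(op_lab = op_lab, ref_sync = ref_sync)
    if (!is.null(ga_op))
      out$series <- c(out$series, list(op_states = ga_op$states,
                                       ref_states = ga_ref$states))
  }
  structure(out, class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("Gait report: lag %d frames; mean node RMS %.1f mm; %d matched steps\n",
              x$lag_frames, x$node_report$mean_mm,
              if (is.null(x$matches$pairs)) 0L else nrow(x$matches$pairs)))
  if (!is.null(x$gait_error))
    cat("  gait-event stage failed:", x$gait_error, "\n")
  if (!is.null(x$param_report))
    cat(sprintf("  RMS errors: step length %.2f cm, stance %.3f s, swing %.3f s\n",
                x$param_report$step_length_cm, x$param_report$stance_time_s,
                x$param_report$swing_time_s))
  invisible(x)
}

#' Simulate and analyze one batch run
#'
#' Convenience wrapper: builds the configurations of one manifest row,
#' simulates the walk, renders reference and cameras, and runs the full
#' chain.
#'
#' @param row One row of the manifest from [simulate_batch()].
#' @param ... Overrides passed to [gait_config()].
#' @return A `gait_report` (with the `gait_recording` attached as `$truth`).
#' @export
run_manifest_row <- function(row, ...) {
  cfgs <- manifest_configs(row, ...)
  gt <- simulate_walk(cfgs$gait)
  ref <- render_reference(gt, cfgs$scene)
  cams <- render_cameras(gt, cfgs$scene)
  rep <- run_recording(cams$seriesA, cams$seriesB, cams$rig, ref)
  rep$truth <- gt
  rep
}

#' Per-recording error table of a factorial batch
#'
#' Runs the full chain on every recording of a manifest and collects the
#' dependent variables of the factorial analysis: mean node RMS (mm) and
#' the RMS errors of step length (cm), stance and swing time (s), next to
#' the -1/+1 factor codes.
#'
#' @param manifest Manifest from [simulate_batch()].
#' @param ... Overrides passed to [gait_config()].
#'
#' @return Data frame with one row per recording: `run`, `x1`, `x2`, `x3`,
#'   `rms_mm`, `step_length_cm`, `stance_time_s`, `swing_time_s`.
#' @export
batch_error_table <- function(manifest, ...) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    rep <- run_manifest_row(manifest[i, ], ...)
    data.frame(run = manifest$run[i],
               x1 = manifest$x1[i], x2 = manifest$x2[i], x3 = manifest$x3[i],
               rms_mm = rep$node_report$mean_mm,
               step_length_cm = if (is.null(rep$param_report)) NA_real_
                 else rep$param_report$step_length_cm,
               stance_time_s = if (is.null(rep$param_report)) NA_real_
                 else rep$param_report$stance_time_s,
               swing_time_s = if (is.null(rep$param_report)) NA_real_
                 else rep$param_report$swing_time_s)
  })
  do.call(rbind, out)
}

#' Factorial ANOVA over a batch error table
#'
#' One two-level factorial ANOVA per dependent variable (trajectory RMS,
#' step length error, stance and swing time errors).
#'
#' @param error_table Output of [batch_error_table()].
#' @return Named list of `anova_table` objects.
#' @export
batch_anova <- function(error_table) {
  vars <- c(rms_mm = "rms_mm", step_length_cm = "step_length_cm",
            stance_time_s = "stance_time_s", swing_time_s = "swing_time_s")
  lapply(vars, function(v) {
    df <- error_table[!is.na(error_table[[v]]),
                      c("x1", "x2", "x3", v)]
    names(df)[4] <- "xi"
    factorial_anova(df)
  })
}

#' Run the measurement chain from files
#'
#' File-based front end over [run_recording()]: reads the two OpenPose
#' keypoint directories, the calibration JSON and the reference trajectory
#' CSV, runs the chain, and writes every checkpoint (lag, transforms,
#' thresholds, step tables, error report) into `out_dir`.
#'
#' @param camA_dir,camB_dir OpenPose JSON directories of the two cameras.
#' @param calibration_path Calibration JSON.
#' @param reference_path Reference trajectory CSV.
#' @param out_dir Output directory (created if needed).
#' @param ... Passed on to [run_recording()].
#'
#' @return The `gait_report`, invisibly; artifacts on disk.
#' @export
pipeline_run <- function(camA_dir, camB_dir, calibration_path,
                         reference_path, out_dir, ...) {
  for (p in c(camA_dir, camB_dir, calibration_path, reference_path))
    if (!file.exists(p)) stop(sprintf("input not found: '%s'", p))
  sA <- read_openpose_dir(camA_dir, camera_id = "camA")
  sB <- read_openpose_dir(camB_dir, camera_id = "camB")
  rig <- read_calibration(calibration_path)
  ref <- read_trajectory_table(reference_path)
  rep <- run_recording(sA, sB, rig, ref, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_transform(rep$lab_transform, file.path(out_dir, "lab_transform.json"))
  write_transform(rep$eval_transform, file.path(out_dir, "eval_transform.json"))
  if (!is.null(rep$steps_op)) {
    write_step_records(rep$steps_op, file.path(out_dir, "steps_markerless.csv"))
    write_step_records(rep$steps_ref, file.path(out_dir, "steps_reference.csv"))
  }
  report <- list(
    lag_frames = rep$lag_frames,
    node_rms_mm = as.list(rep$node_report$per_node),
    node_rms_mean_mm = rep$node_report$mean_mm,
    node_rms_sd_mm = rep$node_report$sd_mm,
    param_rms = if (is.null(rep$param_report)) NULL else
      list(step_length_cm = rep$param_report$step_length_cm,
           stance_time_s = rep$param_report$stance_time_s,
           swing_time_s = rep$param_report$swing_time_s),
    gait_error = rep$gait_error,
    thresholds = if (is.null(rep$thresholds)) NULL else list(
      op = lapply(rep$thresholds$op, function(t) list(high = t$high, low = t$low)),
      ref = lapply(rep$thresholds$ref, function(t) list(high = t$high, low = t$low))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Simulate a batch to disk
#'
#' Writes every recording of the factorial design (camera JSON dirs,
#' reference CSV, calibration, ground truth) plus the manifest CSV.
#'
#' @param out_dir Output directory.
#' @param replicates,subjects,seed Passed to [simulate_batch()].
#' @param ... Overrides passed to [gait_config()].
#' @return The manifest, invisibly.
#' @export
pipeline_simulate <- function(out_dir, replicates = 3, subjects = 2,
                              seed = 1L, ...) {
  manifest <- simulate_batch(replicates = replicates, subjects = subjects,
                             seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    cfgs <- manifest_configs(manifest[i, ], ...)
    gt <- simulate_walk(cfgs$gait)
    write_recording(gt, cfgs$scene,
                    file.path(out_dir, sprintf("run_%03d", manifest$run[i])))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
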