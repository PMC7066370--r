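# Gait-event detection: ankle-speed estimation, automatic hysteresis
# thresholds, the stance/swing automaton, complete-step trimming and
# spatio-temporal parameters.

ankle_joint <- function(foot) {
  switch(match.arg(foot, c("left", "right")),
         left = "LAnkle", right = "RAnkle")
}

#' Fill short dropout gaps by linear interpolation
#'
#' Joint positions missing for runs of at most `max_gap` frames are linearly
#' interpolated (per coordinate) before filtering; longer gaps are left
#' invalid and later invalidate the gait cycles they overlap.
#'
#' @param series A `skeleton3d`.
#' @param max_gap Longest run of missing frames to bridge (default 5).
#'
#' @return A `skeleton3d` with short gaps filled and marked valid.
#' @export
fill_short_gaps <- function(series, max_gap = 5) {
  xyz <- series$xyz; valid <- series$valid
  n <- dim(xyz)[1]
  for (j in seq_len(dim(xyz)[2])) {
    ok <- valid[, j]
    if (all(ok) || sum(ok) < 2) next
    r <- rle(!ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      a <- starts[g]; b <- ends[g]
      if (a == 1 || b == n || (b - a + 1) > max_gap) next
      w <- (seq(a, b) - (a - 1)) / (b - a + 2)
      for (d in 1:3)
        xyz[a:b, j, d] <- (1 - w) * xyz[a - 1, j, d] + w * xyz[b + 1, j, d]
      valid[a:b, j] <- TRUE
    }
  }
  skeleton3d(xyz, valid, frame_rate = series$frame_rate,
             frame_ref = series$frame_ref, joints = series$joints,
             system_id = series$system_id, t0 = series$t0)
}

#' Ankle speed magnitude
#'
#' Per-frame speed of one ankle: `v_i = f * |p_i - p_{i-1}|` (3D Euclidean
#' displacement times the sampling rate), with the first sample copied from
#' the second. Positions are expected to be low-pass filtered (10 Hz
#' Butterworth) beforehand. Frames adjacent to invalid positions are
#' marked invalid.
#'
#' @param series A `skeleton3d` (filtered coordinates).
#' @param foot `"left"` or `"right"`.
#'
#' @return List of class `speed_series`: `v` (m/s), `valid`, `frame_rate`,
#'   `foot`.
#' @export
ankle_speed <- function(series, foot = c("left", "right")) {
  foot <- match.arg(foot)
  p <- joint_xyz(series, ankle_joint(foot))
  j <- match(ankle_joint(foot), series$joints)
  ok <- series$valid[, j]
  if (sum(ok) < 2) stop("fewer than 2 valid ankle frames")
  n <- nrow(p)
  f <- series$frame_rate
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  v <- c(NA_real_, f * d)
  v[1] <- v[2]
  valid <- c(ok[2] & ok[1], ok[-1] & ok[-n])
  valid[1] <- ok[1] & ok[2]
  structure(list(v = v, valid = valid, frame_rate = f, foot = foot),
            class = "speed_series")
}

#' Automatic hysteresis thresholds from a calibration record
#'
#' Sorts all valid smoothed speeds of a complete gait test ascending and
#' takes the nearest-rank 65th percentile (index `ceiling(0.65 n)`) as the
#' swing-onset threshold; the stance-onset threshold is 80% of it. The two
#' levels give the stance/swing automaton its noise immunity.
#'
#' @param speed A `speed_series` of smoothed speeds spanning both slow and
#'   fast phases.
#'
#' @return List of class `hysteresis_thresholds` with `high` and `low`
#'   (m/s).
#' @export
estimate_thresholds <- function(speed) {
  v <- speed$v[speed$valid & !is.na(speed$v)]
  if (length(v) < 20)
    stop("need at least 20 valid speed samples to calibrate thresholds")
  if (max(v) - min(v) < 1e-12)
    stop("no gait dynamics in calibration record: all speeds equal")
  vs <- sort(v)
  high <- vs[ceiling(0.65 * length(vs))]
  structure(list(high = high, low = 0.8 * high),
            class = "hysteresis_thresholds")
}

#' @export
print.hysteresis_thresholds <- function(x, ...) {
  cat(sprintf("<hysteresis thresholds: swing > %.3f m/s, stance < %.3f m/s>\n",
              x$high, x$low))
  invisible(x)
}

#' Stance/swing detection by velocity hysteresis
#'
#' Scans the smoothed ankle-speed signal in time order: the foot switches
#' to swing (1) when the speed exceeds the high threshold and back to
#' stance (0) when it drops below the low threshold; between the two the
#' state is held, which suppresses chatter from residual noise. The initial
#' state is stance unless the first speed already exceeds the high
#' threshold. Invalid frames inherit the previous state.
#'
#' @param speed A smoothed `speed_series`.
#' @param th A `hysteresis_thresholds`.
#'
#' @return List of class `foot_states`: `state` (integer 0/1 per frame),
#'   `frame_rate`, `foot`.
#' @export
detect_foot_states <- function(speed, th) {
  stopifnot(inherits(th, "hysteresis_thresholds"), th$low < th$high,
            th$low > 0)
  v <- speed$v
  n <- length(v)
  state <- integer(n)
  cur <- if (!is.na(v[1]) && speed$valid[1] && v[1] > th$high) 1L else 0L
  for (i in seq_len(n)) {
    if (speed$valid[i] && !is.na(v[i])) {
      if (v[i] > th$high) cur <- 1L
      else if (v[i] < th$low) cur <- 0L
    }
    state[i] <- cur
  }
  structure(list(state = state, frame_rate = speed$frame_rate,
                 foot = speed$foot),
            class = "foot_states")
}

# Heel strikes: first frames of stance runs (1 -> 0 transitions).
# Toe offs: first frames of swing runs (0 -> 1 transitions).
state_events <- function(states) {
  s <- states$state
  n <- length(s)
  hs <- which(s[-1] == 0L & s[-n] == 1L) + 1L
  to <- which(s[-1] == 1L & s[-n] == 0L) + 1L
  list(heel_strikes = hs, toe_offs = to)
}

#' Trim incomplete step cycles at the recording boundaries
#'
#' Step cycles are delimited by consecutive heel strikes of the foot. The
#' boundary handling distinguishes four cases by the entry and exit state
#' of the recording window: entering and exiting in swing drops the first
#' and last cycle (case 1); entering in stance and exiting in swing drops
#' the last (case 2); entering in swing and exiting in stance drops the
#' first (case 3); entering and exiting in stance keeps every cycle
#' (case 4). A recording yielding no complete cycle returns an empty set.
#'
#' @param states A `foot_states`.
#'
#' @return List with `cycles` (two-column matrix of start/end heel-strike
#'   frames, zero rows when none survive) and `case` (1-4).
#' @export
trim_incomplete <- function(states) {
  s <- states$state
  enter <- s[1]; exit <- s[length(s)]
  case <- if (enter == 1L && exit == 1L) 1L
          else if (enter == 0L && exit == 1L) 2L
          else if (enter == 1L && exit == 0L) 3L
          else 4L
  hs <- state_events(states)$heel_strikes
  if (length(hs) < 2)
    return(list(cycles = matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("start", "end"))),
                case = case))
  cycles <- cbind(start = hs[-length(hs)], end = hs[-1])
  drop_first <- case %in% c(1L, 3L)
  drop_last <- case %in% c(1L, 2L)
  keep <- rep(TRUE, nrow(cycles))
  if (drop_first) keep[1] <- FALSE
  if (drop_last) keep[length(keep)] <- FALSE
  list(cycles = cycles[keep, , drop = FALSE], case = case)
}

#' Spatio-temporal parameters from both feet's state series
#'
#' For every complete cycle of each foot: the heel strike opens the cycle,
#' stance time runs to the toe off, swing time from the toe off to the next
#' heel strike, and step length is the ground-plane distance between the
#' ankle position at the heel strike and the opposite foot's ankle at its
#' immediately preceding heel strike. Heel-strike positions are read from
#' the (filtered) ankle trajectories of `skeleton`, whose x/y plane must be
#' horizontal (lab frame).
#'
#' @param statesL,statesR `foot_states` for the left and right foot.
#' @param skeleton Lab-frame `skeleton3d` the states were derived from.
#'
#' @return Data frame of step records: `foot`, `heel_strike_time_s`,
#'   `heel_strike_x_m`, `heel_strike_y_m`, `step_length_m`,
#'   `stance_time_s`, `swing_time_s`, `stride_time_s`, `complete`.
#' @export
compute_step_parameters <- function(statesL, statesR, skeleton) {
  stopifnot(statesL$foot == "left", statesR$foot == "right")
  f <- statesL$frame_rate
  tm <- skeleton_times(skeleton)
  evL <- state_events(statesL); evR <- state_events(statesR)
  if (length(evL$heel_strikes) >= 2 && length(evR$heel_strikes) >= 2) {
    # alternating gait: the two feet's strikes must interleave in time
    lab <- rep(c(0L, 1L), c(length(evL$heel_strikes), length(evR$heel_strikes)))
    lab <- lab[order(c(evL$heel_strikes, evR$heel_strikes))]
    if (all(diff(lab) >= 0) || all(diff(lab) <= 0))
      stop("single-support sequence implausible: feet's heel strikes never interleave")
  }
  ank <- list(left = joint_xyz(skeleton, "LAnkle"),
              right = joint_xyz(skeleton, "RAnkle"))
  opp_hs <- list(left = evR$heel_strikes, right = evL$heel_strikes)
  rows <- list()
  for (foot in c("left", "right")) {
    states <- if (foot == "left") statesL else statesR
    ev <- state_events(states)
    tr <- trim_incomplete(states)
    if (nrow(tr$cycles) == 0) next
    for (ci in seq_len(nrow(tr$cycles))) {
      h0 <- tr$cycles[ci, 1]; h1 <- tr$cycles[ci, 2]
      to <- ev$toe_offs[ev$toe_offs > h0 & ev$toe_offs < h1]
      if (length(to) != 1) next
      prev_opp <- opp_hs[[foot]][opp_hs[[foot]] < h0]
      step_len <- NA_real_
      if (length(prev_opp) > 0) {
        po <- prev_opp[length(prev_opp)]
        p_here <- ank[[foot]][h0, ]
        p_opp <- ank[[setdiff(c("left", "right"), foot)]][po, ]
        if (!anyNA(p_here) && !anyNA(p_opp))
          step_len <- sqrt(sum((p_here[1:2] - p_opp[1:2])^2))
      }
      pos <- ank[[foot]][h0, ]
      rows[[length(rows) + 1]] <- data.frame(
        foot = foot,
        heel_strike_time_s = tm[h0],
        heel_strike_x_m = pos[1], heel_strike_y_m = pos[2],
        step_length_m = step_len,
        stance_time_s = (to - h0) / f,
        swing_time_s = (h1 - to) / f,
        stride_time_s = (h1 - h0) / f,
        complete = TRUE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(foot = character(0), heel_strike_time_s = numeric(0),
                      heel_strike_x_m = numeric(0), heel_strike_y_m = numeric(0),
                      step_length_m = numeric(0), stance_time_s = numeric(0),
                      swing_time_s = numeric(0), stride_time_s = numeric(0),
                      complete = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$heel_strike_time_s), ]
}
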