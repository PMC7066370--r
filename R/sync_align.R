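# Temporal synchronization via the wrist-to-hip tap gesture and rigid
# spatial alignment (Kabsch) into a common laboratory frame.

#' Resample a skeleton series by cubic-spline interpolation
#'
#' Downsamples (or re-times) each joint coordinate with a cubic spline fit
#' through its valid samples. A resampled point is valid only where the
#' enclosing source samples are valid, so interpolation never bridges
#' dropouts silently.
#'
#' @param series A `skeleton3d`.
#' @param target_rate Target sampling rate in Hz; must not exceed the
#'   source rate.
#'
#' @return A `skeleton3d` at `target_rate` covering the same time span.
#' @export
resample_skeleton <- function(series, target_rate) {
  if (target_rate > series$frame_rate)
    stop("resampling above the source rate is not supported")
  src_t <- skeleton_times(series)
  n <- length(src_t)
  new_t <- seq(src_t[1], src_t[n], by = 1 / target_rate)
  J <- length(series$joints)
  xyz <- array(NA_real_, c(length(new_t), J, 3))
  valid <- matrix(FALSE, length(new_t), J)
  # index of enclosing source samples for each target time
  lo <- findInterval(new_t, src_t, rightmost.closed = TRUE)
  hi <- pmin(lo + 1, n)
  at_knot <- abs(new_t - src_t[lo]) < 1e-9
  for (j in seq_len(J)) {
    ok <- series$valid[, j]
    if (sum(ok) < 4) {
      if (sum(ok) == 0) next
      stop(sprintf("joint '%s' has too few valid samples (%d) to resample",
                   series$joints[j], sum(ok)))
    }
    v_tgt <- (ok[lo] & (at_knot | ok[hi]))
    for (d in 1:3) {
      sf <- stats::splinefun(src_t[ok], series$xyz[ok, j, d], method = "fmm")
      xyz[v_tgt, j, d] <- sf(new_t[v_tgt])
    }
    valid[, j] <- v_tgt
  }
  skeleton3d(xyz, valid, frame_rate = target_rate,
             frame_ref = series$frame_ref, joints = series$joints,
             system_id = series$system_id, t0 = src_t[1])
}

#' Wrist-to-hip gesture signal
#'
#' Per-frame Euclidean distance between the right wrist and right hip joint
#' centers — the scalar signal used to synchronize the markerless and
#' reference streams through the tap gesture performed before each test.
#'
#' @param series A `skeleton3d` containing `RWrist` and `RHip`.
#'
#' @return List with `values` (m; `NA` where either joint is invalid),
#'   `frame_rate` and `source` (the series' system label).
#' @export
gesture_signal <- function(series) {
  w <- joint_xyz(series, "RWrist")
  h <- joint_xyz(series, "RHip")
  d <- sqrt(rowSums((w - h)^2))
  structure(list(values = d, frame_rate = series$frame_rate,
                 source = series$system_id),
            class = "gesture_signal")
}

#' Estimate the integer-frame lag between two gesture signals
#'
#' Maximizes the normalized cross-correlation of the mean-removed signals
#' over their valid overlap. The returned lag is such that
#' `sigA[k]` aligns with `sigB[k + lag]`; ties break toward the smallest
#' absolute lag.
#'
#' @param sigA,sigB Gesture signals (from [gesture_signal()]) at a common
#'   rate.
#' @param max_lag Largest absolute lag searched, in frames.
#'
#' @return Integer lag in frames.
#' @export
estimate_lag <- function(sigA, sigB, max_lag = 90) {
  if (sigA$frame_rate != sigB$frame_rate)
    stop("gesture signals must share a sampling rate")
  a <- sigA$values; b <- sigB$values
  if (stats::var(a, na.rm = TRUE) < 1e-12 || stats::var(b, na.rm = TRUE) < 1e-12)
    stop("no gesture detected: synchronization signal is flat")
  min_overlap <- ceiling(2 * sigA$frame_rate)
  # z-score globally, then slide: the score is the normalized cross
  # correlation of the mean-removed signals; zero-filling outside the
  # overlap keeps short-overlap lags from being spuriously rewarded
  za <- (a - mean(a, na.rm = TRUE)) / stats::sd(a, na.rm = TRUE)
  zb <- (b - mean(b, na.rm = TRUE)) / stats::sd(b, na.rm = TRUE)
  za[is.na(za)] <- 0; zb[is.na(zb)] <- 0
  lags <- seq(-max_lag, max_lag)
  score <- rep(NA_real_, length(lags))
  for (li in seq_along(lags)) {
    lag <- lags[li]
    ia <- seq_along(a)
    ib <- ia + lag
    keep <- ib >= 1 & ib <= length(b)
    ia <- ia[keep]; ib <- ib[keep]
    if (sum(za[ia] != 0 & zb[ib] != 0) < min_overlap) next
    score[li] <- sum(za[ia] * zb[ib])
  }
  if (all(is.na(score)))
    stop("no lag with at least 2 s of valid overlap")
  best <- which(score >= max(score, na.rm = TRUE) - 1e-9)
  lags[best[which.min(abs(lags[best]))]]
}

#' Kabsch rigid registration
#'
#' Closed-form least-squares rotation and translation mapping a source
#' point set onto a target set: SVD of the centered cross-covariance, with
#' the determinant correction that excludes reflections.
#'
#' @param P Source points, N x 3 (m).
#' @param Q Target points, N x 3 (m), row-matched to `P`.
#' @param from_frame,to_frame Frame labels for the returned transform.
#'
#' @return A `rigid_transform` minimizing `sum(|R p + t - q|^2)`.
#' @export
kabsch <- function(P, Q, from_frame = "source", to_frame = "target") {
  P <- matrix(P, ncol = 3); Q <- matrix(Q, ncol = 3)
  keep <- stats::complete.cases(P, Q)
  P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 point correspondences")
  pbar <- colMeans(P); qbar <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pbar), sweep(Q, 2, qbar))
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1))
    stop("degenerate (collinear) point configuration")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qbar - as.numeric(R %*% pbar)
  rigid_transform(R, t, from_frame, to_frame)
}

#' Apply a rigid transform to a skeleton series
#'
#' Maps every valid joint position and relabels the reference frame; the
#' validity mask is untouched.
#'
#' @param series A `skeleton3d` whose `frame_ref` equals `T$from_frame`.
#' @param T A `rigid_transform`.
#'
#' @return The transformed `skeleton3d` in `T$to_frame`.
#' @export
apply_transform <- function(series, T) {
  if (!identical(series$frame_ref, T$from_frame))
    stop(sprintf("series is in frame '%s' but transform maps from '%s'",
                 series$frame_ref, T$from_frame))
  dm <- dim(series$xyz)
  flat <- matrix(series$xyz, ncol = 3)
  out <- sweep(flat %*% t(T$R), 2, T$t, `+`)
  xyz <- array(out, dm)
  skeleton3d(xyz, series$valid, frame_rate = series$frame_rate,
             frame_ref = T$to_frame, joints = series$joints,
             system_id = series$system_id, t0 = series$t0)
}

# Stack all valid (frame x node) correspondences between two synchronized
# equal-rate series. node_map: named character vector, names = joints of
# `op`, values = joints of `ref`.
stack_correspondences <- function(op, ref, node_map = NULL) {
  if (is.null(node_map)) {
    shared <- intersect(intersect(op$joints, ref$joints), eval_nodes())
    node_map <- stats::setNames(shared, shared)
  }
  n <- min(dim(op$xyz)[1], dim(ref$xyz)[1])
  P <- NULL; Q <- NULL; nodes_used <- character(0)
  for (k in seq_along(node_map)) {
    jo <- match(names(node_map)[k], op$joints)
    jr <- match(node_map[[k]], ref$joints)
    if (is.na(jo) || is.na(jr)) next
    ok <- op$valid[seq_len(n), jo] & ref$valid[seq_len(n), jr]
    if (!any(ok)) next
    P <- rbind(P, matrix(op$xyz[seq_len(n), jo, ][ok, ], ncol = 3))
    Q <- rbind(Q, matrix(ref$xyz[seq_len(n), jr, ][ok, ], ncol = 3))
    nodes_used <- c(nodes_used, names(node_map)[k])
  }
  if (length(nodes_used) < 3)
    stop("fewer than 3 distinct nodes with valid correspondences")
  list(P = P, Q = Q, nodes = nodes_used)
}

#' Rigid transform from the markerless frame into the laboratory frame
#'
#' One global Kabsch fit over all valid (frame x node) correspondences
#' between the synchronized markerless series and the reference table. The
#' laboratory frame convention (origin midway between the cameras at ground
#' level, axes of the reference system) is carried by the reference data.
#'
#' @param op_series Markerless `skeleton3d` (e.g. camera-A frame).
#' @param ref_series Reference `skeleton3d` in the lab frame, same rate and
#'   already synchronized.
#' @param node_map Named character vector mapping markerless joints to
#'   reference joints; defaults to the 13 shared evaluation nodes.
#'
#' @return A `rigid_transform` from `op_series$frame_ref` to
#'   `ref_series$frame_ref`.
#' @export
build_lab_transform <- function(op_series, ref_series, node_map = NULL) {
  if (op_series$frame_rate != ref_series$frame_rate)
    stop("series must share a frame rate; resample and synchronize first")
  cs <- stack_correspondences(op_series, ref_series, node_map)
  kabsch(cs$P, cs$Q, from_frame = op_series$frame_ref,
         to_frame = ref_series$frame_ref)
}
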