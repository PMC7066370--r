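# Stereo geometry: forward projection, undistortion, two-view triangulation.

# Apply the Brown-Conrady distortion model to normalized coordinates.
# xn: n x 2 matrix. Returns n x 2 distorted normalized coordinates.
distort_normalized <- function(xn, cam) {
  x <- xn[, 1]; y <- xn[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
  xd <- x * radial + 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
  yd <- y * radial + cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
  cbind(xd, yd)
}

#' Project 3D points in the camera frame to pixel coordinates
#'
#' Pinhole projection with Brown-Conrady radial and tangential distortion:
#' points are normalized by depth, distorted, then mapped through the focal
#' lengths and principal point.
#'
#' @param points n x 3 matrix of camera-frame coordinates (m); z must be
#'   positive (in front of the camera).
#' @param cam A `camera_intrinsics`.
#'
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(points, cam) {
  points <- matrix(points, ncol = 3)
  if (any(points[, 3] <= 0))
    stop("cannot project points at or behind the camera (z <= 0)")
  xn <- points[, 1:2, drop = FALSE] / points[, 3]
  xd <- distort_normalized(xn, cam)
  cbind(u = cam$fx * xd[, 1] + cam$cx,
        v = cam$fy * xd[, 2] + cam$cy)
}

#' Undistort pixel coordinates to normalized image coordinates
#'
#' Inverts the projection model of [project_points()] by fixed-point
#' iteration on the distortion (tolerance 1e-10, at most 50 iterations).
#' Points for which the iteration fails to converge (wild distortion) are
#' returned as `NA` rather than raising an error.
#'
#' @param points n x 2 matrix of pixel coordinates.
#' @param cam A `camera_intrinsics`.
#'
#' @return n x 2 matrix of normalized coordinates; rows are `NA` where the
#'   inversion did not converge.
#' @export
undistort_points <- function(points, cam, tol = 1e-10, max_iter = 50L) {
  points <- matrix(points, ncol = 2)
  xd <- cbind((points[, 1] - cam$cx) / cam$fx,
              (points[, 2] - cam$cy) / cam$fy)
  xn <- xd
  ok <- rep(FALSE, nrow(xd))
  for (it in seq_len(max_iter)) {
    delta <- distort_normalized(xn, cam) - xn
    xn_new <- xd - delta
    step <- sqrt(rowSums((xn_new - xn)^2))
    xn <- xn_new
    ok <- step < tol
    if (all(ok)) break
  }
  xn[!ok, ] <- NA_real_
  colnames(xn) <- c("x", "y")
  xn
}

#' Triangulate one point pair
#'
#' Linear (DLT) two-view triangulation on undistorted normalized
#' observations, with camera matrices `[I|0]` (camera A) and `[R|t]`
#' (camera B). The homogeneous least-squares solution (smallest right
#' singular vector) is dehomogenized to camera-A coordinates.
#'
#' @param ptA,ptB Pixel coordinates (length-2) observed in cameras A and B.
#' @param rig A `stereo_rig`.
#'
#' @return List with `point` (length-3, camera-A frame, m), `residual`
#'   (RMS of the two reprojection errors, px) and `degenerate` (TRUE when
#'   the rays are near parallel and the solution is meaningless).
#' @export
triangulate_pair <- function(ptA, ptB, rig) {
  nA <- undistort_points(rbind(ptA), rig$camA)
  nB <- undistort_points(rbind(ptB), rig$camB)
  if (any(is.na(nA)) || any(is.na(nB)))
    return(list(point = rep(NA_real_, 3), residual = NA_real_,
                degenerate = TRUE))
  PA <- cbind(diag(3), c(0, 0, 0))
  PB <- cbind(rig$R, rig$t)
  A <- rbind(nA[1] * PA[3, ] - PA[1, ],
             nA[2] * PA[3, ] - PA[2, ],
             nB[1] * PB[3, ] - PB[1, ],
             nB[2] * PB[3, ] - PB[2, ])
  s <- svd(A)
  if (s$d[3] - s$d[4] < 1e-12)
    return(list(point = rep(NA_real_, 3), residual = NA_real_,
                degenerate = TRUE))
  Xh <- s$v[, 4]
  if (abs(Xh[4]) < 1e-14)
    return(list(point = rep(NA_real_, 3), residual = NA_real_,
                degenerate = TRUE))
  X <- Xh[1:3] / Xh[4]
  XB <- as.numeric(rig$R %*% X + rig$t)
  if (X[3] <= 0 || XB[3] <= 0)
    return(list(point = X, residual = NA_real_, degenerate = TRUE))
  eA <- sqrt(sum((project_points(rbind(X), rig$camA) - ptA)^2))
  eB <- sqrt(sum((project_points(rbind(XB), rig$camB) - ptB)^2))
  list(point = X, residual = sqrt((eA^2 + eB^2) / 2), degenerate = FALSE)
}

#' Triangulate two synchronized keypoint series into a 3D skeleton
#'
#' Per frame and per joint, both observations must be present (non-zero
#' confidence) and the triangulation non-degenerate for the 3D position to
#' be valid. The output is expressed in the camera-A frame.
#'
#' @param seriesA,seriesB `keypoint_series` of equal length and rate,
#'   already mutually synchronized.
#' @param rig A `stereo_rig`.
#'
#' @return A `skeleton3d` with `frame_ref = "cameraA"`.
#' @export
triangulate_series <- function(seriesA, seriesB, rig) {
  if (n_frames(seriesA) != n_frames(seriesB))
    stop("series lengths differ; synchronize the two camera streams first")
  if (seriesA$frame_rate != seriesB$frame_rate)
    stop("series frame rates differ; synchronize the two camera streams first")
  n <- n_frames(seriesA)
  xyz <- array(NA_real_, c(n, 18, 3))
  valid <- matrix(FALSE, n, 18)
  obs_ok <- seriesA$conf > 0 & seriesB$conf > 0
  idx <- which(obs_ok)
  if (length(idx) > 0) {
    nA <- undistort_points(cbind(seriesA$u[idx], seriesA$v[idx]), rig$camA)
    nB <- undistort_points(cbind(seriesB$u[idx], seriesB$v[idx]), rig$camB)
    PB <- cbind(rig$R, rig$t)
    for (k in seq_along(idx)) {
      if (any(is.na(nA[k, ])) || any(is.na(nB[k, ]))) next
      A <- rbind(c(-1, 0, nA[k, 1], 0),
                 c(0, -1, nA[k, 2], 0),
                 nB[k, 1] * PB[3, ] - PB[1, ],
                 nB[k, 2] * PB[3, ] - PB[2, ])
      s <- svd(A, nu = 0)
      if (s$d[3] - s$d[4] < 1e-12) next
      Xh <- s$v[, 4]
      if (abs(Xh[4]) < 1e-14) next
      X <- Xh[1:3] / Xh[4]
      if (X[3] <= 0 || sum(PB[3, ] * c(X, 1)) <= 0) next
      i <- (idx[k] - 1) %% n + 1
      j <- (idx[k] - 1) %/% n + 1
      xyz[i, j, ] <- X
      valid[i, j] <- TRUE
    }
  }
  skeleton3d(xyz, valid, frame_rate = seriesA$frame_rate,
             frame_ref = "cameraA", system_id = "markerless")
}

#' Pooled RMS reprojection error
#'
#' Projects reconstructed 3D points back into both cameras and reports the
#' RMS pixel distance to the observations, pooled over the two views.
#'
#' @param points3D n x 3 matrix in the camera-A frame (m).
#' @param obsA,obsB n x 2 matrices of observed pixel coordinates; rows with
#'   any `NA` are excluded.
#' @param rig A `stereo_rig`.
#'
#' @return RMS reprojection error in pixels.
#' @export
reprojection_rms <- function(points3D, obsA, obsB, rig) {
  points3D <- matrix(points3D, ncol = 3)
  obsA <- matrix(obsA, ncol = 2); obsB <- matrix(obsB, ncol = 2)
  keep <- stats::complete.cases(points3D, obsA, obsB)
  if (!any(keep)) stop("no valid observations to compute reprojection error")
  X <- points3D[keep, , drop = FALSE]
  XB <- t(rig$R %*% t(X) + rig$t)
  dA <- project_points(X, rig$camA) - obsA[keep, , drop = FALSE]
  dB <- project_points(XB, rig$camB) - obsB[keep, , drop = FALSE]
  sqrt(mean(c(rowSums(dA^2), rowSums(dB^2))))
}
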