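test_that("projection maps the optical axis to the principal point", {
  cam <- camera_intrinsics(1000, 1000, 640, 360, 1280, 720,
                           k1 = -0.2, k2 = 0.05, p1 = 1e-3, p2 = -1e-3)
  expect_equal(as.numeric(project_points(c(0, 0, 2), cam)), c(640, 360))
  # pure pinhole arithmetic with no distortion
  cam0 <- camera_intrinsics(1000, 1000, 640, 360, 1280, 720)
  expect_equal(as.numeric(project_points(c(1, 0, 1), cam0)), c(1640, 360))
  expect_error(project_points(c(0, 0, -1), cam0), "behind")
})

test_that("undistortion inverts the forward model on a grid", {
  cam <- camera_intrinsics(820, 818, 656, 368, 1312, 736,
                           k1 = -0.1, k2 = 0.03, k3 = -0.005,
                           p1 = 5e-4, p2 = -3e-4)
  g <- seq(-0.35, 0.35, length.out = 10)
  xn <- as.matrix(expand.grid(x = g, y = g))
  px <- project_points(cbind(xn, 1), cam)
  back <- undistort_points(px, cam)
  expect_lt(max(abs(back - xn)), 1e-9)
  # principal point maps to the optical axis for any coefficients
  expect_equal(as.numeric(undistort_points(c(656, 368), cam)), c(0, 0))
  # zero distortion: one focal length off the center is one normalized unit
  cam0 <- camera_intrinsics(820, 818, 656, 368, 1312, 736)
  expect_equal(as.numeric(undistort_points(c(656 + 820, 368), cam0)), c(1, 0),
               tolerance = 1e-12)
})

test_that("triangulation is exact on noise-free projections", {
  rig <- make_rig(1.8, distortion = TRUE)
  X <- c(0.9, 0.3, 3.0)
  obs <- project_pair(X, rig)
  tri <- triangulate_pair(obs$A[1, ], obs$B[1, ], rig)
  expect_false(tri$degenerate)
  expect_lt(sqrt(sum((tri$point - X)^2)), 1e-6)
  expect_lt(tri$residual, 1e-6)
})

test_that("1000 random points in the working volume triangulate to 1e-6 m", {
  set.seed(42)
  rig <- make_rig(1.8, distortion = TRUE)
  # 3 x 2 x 2 m working volume centered 4 m in front of the cameras
  X <- cbind(runif(1000, -1.5, 1.5) + 0.9,  # keep inside both frusta
             runif(1000, -1, 1),
             runif(1000, 3, 5))
  obs <- project_pair(X, rig)
  err <- numeric(1000); res <- numeric(1000)
  for (i in 1:1000) {
    tri <- triangulate_pair(obs$A[i, ], obs$B[i, ], rig)
    err[i] <- sqrt(sum((tri$point - X[i, ])^2))
    res[i] <- tri$residual
  }
  expect_lt(max(err), 1e-6)
  expect_lt(max(res), 1e-6)
})

test_that("parallel rays are flagged degenerate", {
  rig <- make_rig(1.8)
  # observation at each camera's principal point: rays parallel, no parallax
  tri <- triangulate_pair(c(656, 368), c(656, 368), rig)
  expect_true(tri$degenerate)
})

test_that("series triangulation propagates validity per joint and frame", {
  rig <- make_rig(1.0)
  sk <- make_skeleton(n = 6)
  # place the figure in front of the cameras (camera frame: z forward, y down)
  xyz <- sk$xyz
  cam_xyz <- xyz
  cam_xyz[, , 2] <- 1.6 - xyz[, , 3]   # y down
  cam_xyz[, , 3] <- 3 + xyz[, , 1]     # z forward
  cam_xyz[, , 1] <- xyz[, , 2] + 0.9
  n <- dim(cam_xyz)[1]
  mk <- function(drop_joint = NULL, drop_frame = NULL) {
    u <- matrix(NA_real_, n, 18); v <- matrix(NA_real_, n, 18)
    conf <- matrix(0.9, n, 18)
    for (i in seq_len(n)) {
      pA <- project_points(cam_xyz[i, , ], rig$camA)
      u[i, ] <- pA[, 1]; v[i, ] <- pA[, 2]
    }
    if (!is.null(drop_joint)) {
      conf[drop_frame, drop_joint] <- 0
      u[drop_frame, drop_joint] <- NA
    }
    keypoint_series(u, v, conf)
  }
  mkB <- function(drop_joint = NULL, drop_frame = NULL) {
    u <- matrix(NA_real_, n, 18); v <- matrix(NA_real_, n, 18)
    conf <- matrix(0.9, n, 18)
    for (i in seq_len(n)) {
      XB <- t(rig$R %*% t(cam_xyz[i, , ]) + rig$t)
      pB <- project_points(XB, rig$camB)
      u[i, ] <- pB[, 1]; v[i, ] <- pB[, 2]
    }
    if (!is.null(drop_joint)) {
      conf[drop_frame, drop_joint] <- 0
      u[drop_frame, drop_joint] <- NA
    }
    keypoint_series(u, v, conf)
  }
  sA <- mk()
  sB <- mkB(drop_joint = match("LAnkle", coco18_joints()), drop_frame = 3)
  out <- triangulate_series(sA, sB, rig)
  j <- match("LAnkle", coco18_joints())
  expect_false(out$valid[3, j])
  expect_true(all(out$valid[-3, j]))
  expect_true(all(out$valid[, -j]))
  ok <- out$valid
  err <- abs(out$xyz - cam_xyz)
  expect_lt(max(err[rep(ok, 3)]), 1e-5)
  expect_identical(out$frame_ref, "cameraA")
})

test_that("length-mismatched series are refused with a synchronization hint", {
  rig <- make_rig()
  u <- matrix(650, 2, 18); conf <- matrix(0.9, 2, 18)
  s2 <- keypoint_series(u, u, conf)
  s3 <- keypoint_series(rbind(u, 650), rbind(u, 650), rbind(conf, 0.9))
  expect_error(triangulate_series(s2, s3, rig), "synchronize")
})

test_that("reprojection RMS matches the hand oracle and noise scale", {
  rig <- make_rig(1.8)
  X <- c(0.5, 0.2, 4)
  obs <- project_pair(X, rig)
  expect_equal(reprojection_rms(X, obs$A, obs$B, rig), 0, tolerance = 1e-9)
  # single point with residuals 3 px and 4 px: RMS = sqrt(12.5)
  obsA <- obs$A + c(3, 0); obsB <- obs$B + c(0, 4)
  expect_equal(reprojection_rms(X, obsA, obsB, rig), sqrt(12.5),
               tolerance = 1e-9)
  # Monte-Carlo: keypoints displaced by 0.5 px on average (0.5/sqrt(2) per
  # component) show up as ~0.5 px pooled RMS
  set.seed(7)
  n <- 1000
  Xn <- cbind(runif(n, 0, 1.8), runif(n, -0.8, 0.8), runif(n, 3, 5))
  obsn <- project_pair(Xn, rig)
  s <- 0.5 / sqrt(2)
  rms <- reprojection_rms(Xn, obsn$A + rnorm(2 * n, 0, s),
                          obsn$B + rnorm(2 * n, 0, s), rig)
  expect_gt(rms, 0.4); expect_lt(rms, 0.6)
  expect_error(reprojection_rms(matrix(numeric(0), ncol = 3),
                                matrix(numeric(0), ncol = 2),
                                matrix(numeric(0), ncol = 2), rig),
               "no valid")
})

test_that("triangulation error shrinks as the baseline grows", {
  set.seed(99)
  n <- 400
  X <- cbind(runif(n, -0.5, 2.3), runif(n, -1, 1), runif(n, 2.5, 5.5))
  errs <- vapply(c(1.0, 1.8), function(b) {
    rig <- make_rig(b)
    obs <- project_pair(X, rig)
    obsA <- obs$A + matrix(rnorm(2 * n), n, 2)
    obsB <- obs$B + matrix(rnorm(2 * n), n, 2)
    e <- numeric(n)
    for (i in seq_len(n)) {
      tri <- triangulate_pair(obsA[i, ], obsB[i, ], rig)
      e[i] <- if (tri$degenerate) NA else sqrt(sum((tri$point - X[i, ])^2))
    }
    mean(e, na.rm = TRUE)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # 1 px noise at 1.8 m baseline, subject 2.5-5.5 m away: median error small
  expect_lt(errs[2], 0.05)
})
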