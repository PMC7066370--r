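test_that("alignment for comparison recovers an exact rigid offset", {
  set.seed(14)
  ref <- make_skeleton(n = 20, frame_ref = "lab", system_id = "reference")
  R <- random_rotation(); t <- c(0.3, 0.1, -0.4)
  op <- ref
  op$xyz <- array(sweep(matrix(ref$xyz, ncol = 3), 2, t) %*% R, dim(ref$xyz))
  op$frame_ref <- "cameraA"; op$system_id <- "markerless"
  out <- align_for_comparison(op, ref)
  expect_lt(max(abs(out$aligned$xyz - ref$xyz)), 1e-9)
  rep <- node_rms(out$aligned, ref)
  expect_true(all(rep$per_node < 1e-6))
})

test_that("alignment never increases the total squared distance", {
  set.seed(15)
  ref <- make_skeleton(n = 50, frame_ref = "lab")
  op <- ref
  op$xyz <- op$xyz + array(rnorm(length(op$xyz), 0, 0.02), dim(op$xyz))
  op$frame_ref <- "cameraA"
  before <- sum((op$xyz - ref$xyz)^2)
  out <- align_for_comparison(op, ref)
  after <- sum((out$aligned$xyz - ref$xyz)^2)
  expect_lte(after, before + 1e-12)
  # isotropic noise: per-node RMS close to the injected sigma
  rep <- node_rms(out$aligned, ref)
  sigma3 <- sqrt(3) * 0.02 * 1000
  expect_true(all(abs(rep$per_node - sigma3) / sigma3 < 0.15))
})

test_that("node RMS matches the 3-4-5 hand oracle with alignment frozen", {
  ref <- make_skeleton(n = 25, frame_ref = "lab")
  op <- ref
  j <- match("RKnee", coco18_joints())
  op$xyz[, j, 1] <- op$xyz[, j, 1] + 0.003
  op$xyz[, j, 2] <- op$xyz[, j, 2] + 0.004
  rep <- node_rms(op, ref)   # no alignment applied: offset is preserved
  expect_equal(unname(rep$per_node["RKnee"]), 5, tolerance = 1e-9)
  expect_equal(rep$mean_mm, mean(rep$per_node), tolerance = 1e-9)
  # invariant under a common rigid transform of both systems
  T <- rigid_transform(random_rotation(), c(1, 2, 3), "lab", "lab2")
  rep2 <- node_rms(apply_transform(op, T), apply_transform(ref, T))
  expect_equal(rep2$per_node, rep$per_node, tolerance = 1e-9)
  # a node with no valid frames is absent, not zero
  op$valid[, j] <- FALSE
  rep3 <- node_rms(op, ref)
  expect_true(is.na(rep3$per_node["RKnee"]))
})

mk_steps <- function(times, foot = "right", sl = 0.6, st = 0.72, sw = 0.48) {
  data.frame(foot = foot, heel_strike_time_s = times,
             heel_strike_x_m = 0, heel_strike_y_m = 0,
             step_length_m = sl, stance_time_s = st, swing_time_s = sw,
             stride_time_s = st + sw, complete = TRUE)
}

test_that("step matching pairs by nearest heel-strike time within 0.25 s", {
  ref <- rbind(mk_steps(c(1, 2.2, 3.4)), mk_steps(c(1.6, 2.8), foot = "left"))
  m <- match_steps(ref, ref)
  expect_equal(nrow(m$pairs), 5)
  expect_length(m$unmatched_op, 0)
  expect_length(m$unmatched_ref, 0)
  expect_equal(m$pairs$op_heel_strike_time_s, m$pairs$ref_heel_strike_time_s)
  # jittered events still fully match
  op <- ref; op$heel_strike_time_s <- op$heel_strike_time_s +
    c(0.1, -0.1, 0.08, -0.06, 0.1)
  m2 <- match_steps(op, ref)
  expect_equal(nrow(m2$pairs), 5)
  # a missing markerless step leaves its reference partner unmatched
  m3 <- match_steps(ref[-2, ], ref)
  expect_equal(nrow(m3$pairs), 4)
  expect_length(m3$unmatched_ref, 1)
})

test_that("parameter errors and Bland-Altman match the hand oracle", {
  ref <- rbind(mk_steps(c(1, 2.2)), mk_steps(1.6, foot = "left"))
  op <- ref
  op$step_length_m <- op$step_length_m + c(-0.01, 0, -0.01)
  m <- match_steps(op, ref)
  pe <- param_errors(m$pairs)
  expect_equal(pe$step_length_cm, sqrt(mean(c(1, 0, 1))), tolerance = 1e-9)
  expect_equal(pe$stance_time_s, 0)
  ba <- bland_altman(m$pairs, "step_length_m")
  expect_equal(ba$bias * 100, -2 / 3, tolerance = 1e-3)
  expect_equal(ba$sd * 100, 0.5774, tolerance = 1e-3)
  expect_equal(ba$loa_low * 100, -1.798, tolerance = 1e-3)
  expect_equal(ba$loa_high * 100, 0.465, tolerance = 1e-3)
  # antisymmetry of the bias
  m_rev <- match_steps(ref, op)
  ba_rev <- bland_altman(m_rev$pairs, "step_length_m")
  expect_equal(ba_rev$bias, -ba$bias, tolerance = 1e-12)
  expect_error(bland_altman(m$pairs[1:2, ], "step_length_m"), "at least 3")
})

test_that("an injected constant step-length bias is recovered", {
  set.seed(16)
  ref <- rbind(mk_steps(seq(1, 6, by = 1.2)),
               mk_steps(seq(1.6, 6, by = 1.2), foot = "left"))
  op <- ref
  op$step_length_m <- op$step_length_m - 0.015 + rnorm(nrow(op), 0, 0.002)
  ba <- bland_altman(match_steps(op, ref)$pairs, "step_length_m")
  expect_equal(ba$bias * 100, -1.5, tolerance = 0.2)
})

test_that("factorial ANOVA matches a normal-equations OLS oracle", {
  set.seed(17)
  grid <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  tab <- grid[rep(seq_len(8), 3), ]
  tab$xi <- 1 + 0.5 * tab$x1 - 0.3 * tab$x2 + 2 * tab$x3 +
    0.2 * tab$x1 * tab$x2 + rnorm(24, 0, 0.1)
  fit <- factorial_anova(tab)
  # independent oracle: solve the normal equations directly
  X <- cbind(1, tab$x1, tab$x2, tab$x3, tab$x1 * tab$x2)
  beta <- solve(t(X) %*% X, t(X) %*% tab$xi)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit$effects$estimate, beta[2:5], tolerance = 1e-9,
               ignore_attr = TRUE)
  resid <- tab$xi - X %*% beta
  s2 <- sum(resid^2) / (24 - 5)
  Fs <- beta[2:5]^2 / (s2 * diag(solve(t(X) %*% X))[2:5])
  expect_equal(fit$effects$F, Fs, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$effects$p,
               pf(Fs, 1, 19, lower.tail = FALSE), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a constant response yields zero F and p = 1 everywhere", {
  grid <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  tab <- grid[rep(seq_len(8), 2), ]
  tab$xi <- 5
  fit <- factorial_anova(tab)
  expect_true(all(fit$effects$F == 0))
  expect_true(all(fit$effects$p == 1))
})

test_that("a strong single factor is detected and inert factors are not", {
  set.seed(18)
  grid <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  hits13 <- hits12 <- 0
  for (k in 1:100) {
    tab <- grid[rep(seq_len(8), 3), ]
    tab$xi <- 2 * tab$x3 + rnorm(24, 0, 0.1)
    fit <- factorial_anova(tab)
    if (fit$effects$p[fit$effects$term == "x3"] < 0.001) hits13 <- hits13 + 1
    if (all(fit$effects$p[fit$effects$term %in% c("x1", "x2")] > 0.05))
      hits12 <- hits12 + 1
  }
  expect_equal(hits13, 100)
  expect_gte(hits12, 85)
})

test_that("type-I error of each effect is calibrated under the null", {
  set.seed(19)
  grid <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  n_sim <- 500
  rej <- matrix(FALSE, n_sim, 4)
  for (k in seq_len(n_sim)) {
    tab <- grid[rep(seq_len(8), 3), ]
    tab$xi <- rnorm(24)
    rej[k, ] <- factorial_anova(tab)$effects$p < 0.05
  }
  rate <- colMeans(rej)
  expect_true(all(rate > 0.02 & rate < 0.09))
})

test_that("degenerate designs are refused", {
  tab <- data.frame(x1 = c(-1, -1, -1, -1), x2 = c(-1, -1, 1, 1),
                    x3 = c(-1, 1, -1, 1), xi = rnorm(4))
  expect_error(factorial_anova(tab), "singular|identifiable")
  expect_error(factorial_anova(data.frame(x1 = 0.5, x2 = 1, x3 = 1, xi = 1)),
               "coded")
})
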