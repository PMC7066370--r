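make_speed <- function(v, valid = rep(TRUE, length(v)), fs = 30,
                       foot = "right") {
  structure(list(v = v, valid = valid, frame_rate = fs, foot = foot),
            class = "speed_series")
}

test_that("ankle speed is the per-frame displacement rate", {
  sk <- make_skeleton(n = 10, drift = c(0, 0, 0))
  expect_equal(ankle_speed(sk, "right")$v, rep(0, 10))
  # 0.04 m advance per frame at 30 Hz = 1.2 m/s
  sk2 <- make_skeleton(n = 10, drift = c(0.04, 0, 0))
  v <- ankle_speed(sk2, "left")$v
  expect_equal(v, rep(1.2, 10), tolerance = 1e-9)
  # frames adjacent to an invalid position are invalid
  sk2$valid[4, match("LAnkle", coco18_joints())] <- FALSE
  vv <- ankle_speed(sk2, "left")
  expect_false(vv$valid[4]); expect_false(vv$valid[5])
  expect_true(vv$valid[3]); expect_true(vv$valid[6])
})

test_that("threshold estimation is the nearest-rank 65th percentile", {
  th <- estimate_thresholds(make_speed(sample(1:100)))
  expect_equal(th$high, 65)
  expect_equal(th$low, 52)
  # enumeration oracle across sizes: index is ceiling(0.65 n) of the sort
  for (n in c(20, 21, 37, 64, 100, 101)) {
    set.seed(n)
    v <- runif(n, 0, 3)
    th <- estimate_thresholds(make_speed(v))
    expect_equal(th$high, sort(v)[ceiling(0.65 * n)])
    expect_equal(th$low, 0.8 * th$high, tolerance = 1e-12)
    expect_lte(abs(mean(v <= th$high) - 0.65), 1 / n)
  }
  expect_error(estimate_thresholds(make_speed(rep(1, 50))), "no gait dynamics")
  expect_error(estimate_thresholds(make_speed(1:10)), "at least 20")
})

test_that("threshold scaling follows the speed scale and states are unchanged", {
  set.seed(21)
  v <- abs(sin(seq(0, 10, by = 1 / 30))) * 2
  th1 <- estimate_thresholds(make_speed(v))
  th2 <- estimate_thresholds(make_speed(3.7 * v))
  expect_equal(th2$high, 3.7 * th1$high, tolerance = 1e-12)
  expect_equal(th2$low, 3.7 * th1$low, tolerance = 1e-12)
  s1 <- detect_foot_states(make_speed(v), th1)
  s2 <- detect_foot_states(make_speed(3.7 * v), th2)
  expect_identical(s1$state, s2$state)
})

test_that("the hysteresis automaton switches at the block boundaries", {
  v <- rep(c(0, 10), each = 10, times = 3)
  th <- structure(list(high = 5, low = 4), class = "hysteresis_thresholds")
  st <- detect_foot_states(make_speed(v), th)
  expect_identical(st$state, rep(c(0L, 1L), each = 10, times = 3))
  # all below the low threshold: pure stance
  st0 <- detect_foot_states(make_speed(rep(1, 30)), th)
  expect_identical(st0$state, rep(0L, 30))
  # dip into the dead band after swing onset: hysteresis holds the state
  vd <- c(rep(0, 5), rep(10, 5), rep(4.5, 5), rep(10, 5), rep(0, 5))
  std <- detect_foot_states(make_speed(vd), th)
  expect_identical(std$state, c(rep(0L, 5), rep(1L, 15), rep(0L, 5)))
  # initial state follows the first sample against the high threshold
  expect_identical(detect_foot_states(make_speed(c(10, 10, 0)), th)$state[1], 1L)
  # invalid frames inherit the previous state
  vi <- make_speed(c(0, 0, 10, 10, 0, 0), valid = c(T, T, T, F, F, T))
  expect_identical(detect_foot_states(vi, th)$state, c(0L, 0L, 1L, 1L, 1L, 0L))
})

test_that("hysteresis never chatters more than a single-threshold detector", {
  set.seed(33)
  for (k in 1:20) {
    v <- pmax(0, 2 * sin(seq(0, 8 * pi, length.out = 300)) + rnorm(300, 0, 0.8))
    th <- estimate_thresholds(make_speed(v))
    st <- detect_foot_states(make_speed(v), th)
    mid <- (th$high + th$low) / 2
    single <- as.integer(v > mid)
    expect_lte(sum(diff(st$state) != 0), sum(diff(single) != 0))
  }
})

test_that("complete-step trimming follows the four boundary cases", {
  blocks <- function(...) {
    spec <- list(...)
    unlist(lapply(spec, function(b) rep(b[1], b[2])))
  }
  mk <- function(s) structure(list(state = as.integer(s), frame_rate = 30,
                                   foot = "right"), class = "foot_states")
  # enter 0 / exit 0: all cycles kept (case 4)
  s4 <- blocks(c(0, 5), c(1, 5), c(0, 5), c(1, 5), c(0, 5))
  tr4 <- trim_incomplete(mk(s4))
  expect_identical(tr4$case, 4L)
  expect_identical(nrow(tr4$cycles), 1L)   # two heel strikes: one cycle
  # enter 1 / exit 1 with interior steps: drop first and last (case 1)
  s1 <- blocks(c(1, 5), c(0, 5), c(1, 5), c(0, 5), c(1, 5), c(0, 5),
               c(1, 5), c(0, 5), c(1, 5))
  tr1 <- trim_incomplete(mk(s1))
  expect_identical(tr1$case, 1L)
  expect_identical(nrow(tr1$cycles), 1L)   # 4 strikes: 3 cycles, 2 dropped
  # enter 0 / exit 1: drop last (case 2)
  s2 <- blocks(c(0, 5), c(1, 5), c(0, 5), c(1, 5), c(0, 5), c(1, 5),
               c(0, 5), c(1, 5))
  tr2 <- trim_incomplete(mk(s2))
  expect_identical(tr2$case, 2L)
  expect_identical(nrow(tr2$cycles), 1L)
  # enter 1 / exit 0: drop first (case 3)
  s3 <- blocks(c(1, 5), c(0, 5), c(1, 5), c(0, 5), c(1, 5), c(0, 5))
  tr3 <- trim_incomplete(mk(s3))
  expect_identical(tr3$case, 3L)
  expect_identical(nrow(tr3$cycles), 1L)
  # pure stance: no transitions, zero cycles, not an error
  tr0 <- trim_incomplete(mk(rep(0, 20)))
  expect_identical(nrow(tr0$cycles), 0L)
})

test_that("step parameters follow hand-constructed event times", {
  fs <- 30
  n <- 30 * 3  # 3 s
  tm <- (seq_len(n) - 1) / fs
  # left foot: heel strikes at 1.0 s and 2.0 s, toe off at 1.6 s
  stL <- integer(n)
  stL[tm >= 0.6 & tm < 1.0] <- 1L
  stL[tm >= 1.6 & tm < 2.0] <- 1L
  # right foot: heel strikes at 0.5 s and 1.5 s and 2.5 s, toe offs 0.4 off
  stR <- integer(n)
  stR[tm >= 0.1 & tm < 0.5] <- 1L
  stR[tm >= 1.1 & tm < 1.5] <- 1L
  stR[tm >= 2.1 & tm < 2.5] <- 1L
  mk <- function(s, foot) structure(list(state = s, frame_rate = fs,
                                         foot = foot), class = "foot_states")
  sk <- make_skeleton(n = n, drift = c(0, 0, 0))
  # plant the ankles at known ground positions at the heel strikes
  iL <- match("LAnkle", coco18_joints()); iR <- match("RAnkle", coco18_joints())
  sk$xyz[, iL, 1] <- 1.0; sk$xyz[, iL, 2] <- 0
  sk$xyz[, iR, 1] <- 0.4; sk$xyz[, iR, 2] <- 0
  steps <- compute_step_parameters(mk(stL, "left"), mk(stR, "right"), sk)
  left <- steps[steps$foot == "left", ]
  expect_equal(nrow(left), 1L)
  expect_equal(left$heel_strike_time_s, 1.0)
  expect_equal(left$stance_time_s, 0.6, tolerance = 1e-9)
  expect_equal(left$swing_time_s, 0.4, tolerance = 1e-9)
  expect_equal(left$stride_time_s, 1.0, tolerance = 1e-9)
  # step length: left ankle at (1, 0) vs right ankle at (0.4, 0) -> 0.6 m
  expect_equal(left$step_length_m, 0.6, tolerance = 1e-9)
  # stance + swing equals the stride duration on every record
  expect_equal(steps$stance_time_s + steps$swing_time_s, steps$stride_time_s,
               tolerance = 1e-9)
})

test_that("non-interleaving feet are rejected", {
  fs <- 30; n <- 120
  st <- integer(n)
  st[c(20:29, 50:59, 80:89)] <- 1L
  early <- integer(n); early[c(5:9, 15:19)] <- 1L
  mk <- function(s, foot) structure(list(state = as.integer(s),
                                         frame_rate = fs, foot = foot),
                                    class = "foot_states")
  sk <- make_skeleton(n = n, drift = c(0, 0, 0))
  expect_error(compute_step_parameters(mk(early, "left"), mk(st, "right"), sk),
               "interleave")
})

test_that("short dropout gaps are bridged linearly, long gaps kept invalid", {
  sk <- make_skeleton(n = 20, drift = c(0.1, 0, 0))
  j <- match("RAnkle", coco18_joints())
  truth <- sk$xyz[, j, 1]
  sk$valid[6:8, j] <- FALSE; sk$xyz[6:8, j, ] <- NA       # 3-frame gap
  sk$valid[12:18, j] <- FALSE; sk$xyz[12:18, j, ] <- NA   # 7-frame gap
  out <- fill_short_gaps(sk, max_gap = 5)
  expect_true(all(out$valid[6:8, j]))
  expect_equal(out$xyz[6:8, j, 1], truth[6:8], tolerance = 1e-12)
  expect_true(all(!out$valid[12:18, j]))
})
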