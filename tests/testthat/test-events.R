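test_that("relative signal is foot minus hip centre along the progression axis", {
  n <- 90
  pos <- list(left_hip = cbind(rep(100, n), 300),
              right_hip = cbind(rep(120, n), 300),
              left_ankle = cbind(rep(110, n), 600),
              left_heel = cbind(rep(100, n), 620),
              left_foot_index = cbind(rep(160, n), 640),
              right_heel = cbind(rep(100, n), 620),
              right_foot_index = cbind(rep(160, n), 640))
  tr <- make_multi_traj(pos)
  sig <- relative_ankle_signal(tr, "left")
  expect_equal(sig$value, rep(0, n))  # ankle at the hip centre

  pos$left_ankle <- cbind(rep(160, n), 600)  # 50 px ahead, toes point +x
  sig2 <- relative_ankle_signal(make_multi_traj(pos), "left")
  expect_equal(sig2$value, rep(50, n))

  pos2 <- pos
  expect_error(relative_ankle_signal(make_multi_traj(pos2[-3]), "left"), "missing")
})

test_that("peaks of a sinusoid are labelled heel strikes at the correct period", {
  fs <- 30; t <- (0:299) / fs
  x <- sin(2 * pi * t)  # period exactly 1 s
  ev <- detect_events(x, frame_rate = fs, side = "left")
  expect_gt(length(ev$heel_strikes), 7)
  expect_equal(diff(ev$heel_strikes), rep(1, length(ev$heel_strikes) - 1),
               tolerance = 1 / fs / 1)  # within one frame
  # maxima of sin at t = 0.25 + k
  expect_true(all(abs((ev$heel_strikes - 0.25) %% 1) < 1.5 / fs |
                    abs(((ev$heel_strikes - 0.25) %% 1) - 1) < 1.5 / fs))
  expect_warning(ev0 <- detect_events(rep(1, 100), frame_rate = fs, side = "left"),
                 "fewer than 2")
  expect_length(ev0$heel_strikes, 0)
})

test_that("negating the signal swaps heel-strike and toe-off labels exactly", {
  set.seed(11)
  fs <- 30; t <- (0:449) / fs
  x <- sin(2 * pi * t / 1.2) + 0.3 * sin(4 * pi * t / 1.2 + 1)
  a <- detect_events(x, frame_rate = fs, side = "left")
  b <- detect_events(-x, frame_rate = fs, side = "left")
  expect_equal(a$heel_strikes, b$toe_offs)
  expect_equal(a$toe_offs, b$heel_strikes)
})

test_that("shifting the signal in time shifts every event equally", {
  fs <- 30; t <- (0:299) / fs
  x <- sin(2 * pi * t / 1.1)
  sig <- structure(list(time_s = t, value = x, frame_rate = fs, side = "left"),
                   class = "gait_signal")
  sig_shift <- sig; sig_shift$time_s <- t + 3.7
  a <- detect_events(sig)
  b <- detect_events(sig_shift)
  expect_equal(b$heel_strikes, a$heel_strikes + 3.7)
  expect_equal(b$toe_offs, a$toe_offs + 3.7)
})

test_that("detection hits simulator ground truth within one frame across conditions", {
  for (stride in c(0.9, 1.1, 1.3)) for (sigma in c(0, 2)) {
    s <- simulate_gait(gait_spec(stride_time = stride, duration_s = 15),
                       noise = gait_noise(jitter_sd = sigma, spike_rate = 0),
                       seed = round(1000 * stride + sigma))
    a <- analyze_trajectory(s$traj, calib = sim_lateral_calib(s$truth$spec))
    for (side in c("left", "right")) {
      gt <- s$truth$events[[side]]$heel_strikes
      det <- a$events[[side]]$heel_strikes
      # recall and precision 1 at +-1 frame tolerance (ends may be trimmed)
      core <- gt[gt > 1 & gt < 14]
      m <- match_cycles(core, det, tol_s = 1 / 30 + 1e-9)
      expect_equal(nrow(m), length(core),
                   label = sprintf("stride %.1f sigma %d side %s recall", stride, sigma, side))
      expect_true(all(abs(m$dt) <= 1 / 30 + 1e-9))
      expect_lte(length(det), length(gt) + 1)  # no spurious extras
    }
  }
})

test_that("bilateral pairing validates alternation and extracts cycles", {
  L <- gait_events("left", heel_strikes = c(0, 1, 2), toe_offs = c(0.62, 1.62))
  R <- gait_events("right", heel_strikes = c(0.5, 1.5), toe_offs = c(0.12, 1.12))
  cyc <- pair_bilateral(L, R)
  lcyc <- cyc[cyc$side == "left", ]
  expect_equal(nrow(lcyc), 2)
  expect_equal(lcyc$hs_contra, c(0.5, 1.5))
  expect_equal(lcyc$to[1], 0.62)
  expect_equal(lcyc$to_contra[1], 0.12)

  expect_error(pair_bilateral(L, gait_events("right")), "heel strikes")

  # two consecutive left strikes with no right strike between: cycle dropped
  L2 <- gait_events("left", heel_strikes = c(0, 1, 2, 3))
  R2 <- gait_events("right", heel_strikes = c(0.5, 2.5))
  cyc2 <- pair_bilateral(L2, R2)
  expect_false(any(cyc2$side == "left" & cyc2$hs == 1))  # (1,2) has no contra
  expect_true(any(cyc2$side == "left" & cyc2$hs == 0))
})
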