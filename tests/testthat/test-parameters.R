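test_that("temporal parameters follow their definitions exactly", {
  L <- gait_events("left", heel_strikes = c(0, 1, 2), toe_offs = c(0.62, 1.62))
  R <- gait_events("right", heel_strikes = c(0.5, 1.5), toe_offs = c(0.12, 1.12))
  tp <- temporal_params(pair_bilateral(L, R))
  l1 <- tp[tp$side == "left" & tp$hs == 0, ]
  expect_equal(l1$stride_time, 1.0)
  expect_equal(l1$step_time, 0.5)
  expect_equal(l1$stance_time, 0.62)
  expect_equal(l1$swing_time, 0.38)
  expect_equal(l1$double_support_time, 0.24)
  expect_equal(l1$cadence, 120)
  # stance + swing = stride exactly, for every cycle
  ok <- !is.na(tp$stance_time)
  expect_identical(tp$stance_time[ok] + tp$swing_time[ok], tp$stride_time[ok])
})

test_that("perfectly symmetric gait yields identical left and right parameters", {
  hsL <- seq(0, 10, by = 1); hsR <- hsL + 0.5
  L <- gait_events("left", heel_strikes = hsL, toe_offs = hsL[-length(hsL)] + 0.62)
  R <- gait_events("right", heel_strikes = hsR, toe_offs = hsR[-length(hsR)] + 0.62)
  tp <- temporal_params(pair_bilateral(L, R))
  for (p in c("stride_time", "step_time", "stance_time", "swing_time",
              "double_support_time", "cadence")) {
    lv <- tp[[p]][tp$side == "left"]; rv <- tp[[p]][tp$side == "right"]
    n <- min(sum(!is.na(lv)), sum(!is.na(rv)))
    expect_equal(sort(lv[!is.na(lv)])[1:n], sort(rv[!is.na(rv)])[1:n],
                 label = p)
  }
})

test_that("a cycle without its toe-off keeps stride and step, drops the rest", {
  L <- gait_events("left", heel_strikes = c(0, 1, 2), toe_offs = 1.62)
  R <- gait_events("right", heel_strikes = c(0.5, 1.5), toe_offs = c(0.12, 1.12))
  tp <- temporal_params(pair_bilateral(L, R))
  l1 <- tp[tp$side == "left" & tp$hs == 0, ]
  expect_equal(l1$stride_time, 1)
  expect_true(is.na(l1$stance_time) && is.na(l1$swing_time))
})

test_that("step length and speed follow the calibrated heel separation", {
  n <- 200; fs <- 30
  pos <- list(left_hip = cbind(rep(300, n), 300),
              right_hip = cbind(rep(300, n), 300),
              left_heel = cbind(rep(330, n), 600),
              right_heel = cbind(rep(270, n), 600))  # 60 px apart
  tr <- make_multi_traj(pos, fps = fs)
  hsL <- c(0, 1, 2, 3); hsR <- hsL + 0.5
  cyc <- pair_bilateral(gait_events("left", hsL, hsL[-4] + 0.62),
                        gait_events("right", hsR, hsR[-4] + 0.62))
  sp <- spatial_params(tr, cyc, calibrate_scale(c(0, 0), c(100, 0), 1))
  expect_equal(unique(round(sp$step_length, 10)), 0.6)
  expect_equal(unique(round(sp$step_time, 10)), 0.5)
  expect_equal(sp$gait_speed, sp$step_length / sp$step_time)  # identity

  # degenerate zero separation: step excluded and flagged
  pos$right_heel <- pos$left_heel
  sp0 <- spatial_params(make_multi_traj(pos, fps = fs), cyc,
                        calibrate_scale(c(0, 0), c(100, 0), 1))
  expect_equal(nrow(sp0), 0)
  expect_gt(nrow(attr(sp0, "excluded")), 0)

  # near-frontal view refuses spatial parameters
  trf <- make_multi_traj(pos, view = "near_frontal")
  expect_error(spatial_params(trf, cyc), "near-frontal")
  # video without calibration refuses too
  expect_error(spatial_params(tr, cyc), "calibration")
})

test_that("treadmill orientation is stable under noise (stance stays ~62%)", {
  # hip wobble must never flip the progression sign and swap HS/TO labels
  for (seed in 1:6) {
    s <- simulate_gait(gait_spec(duration_s = 12),
                       noise = gait_noise(jitter_sd = 2), seed = seed)
    a <- analyze_trajectory(s$traj, calib = sim_lateral_calib(s$truth$spec))
    st <- a$temporal$stance_time
    expect_true(all(abs(st[!is.na(st)] - 0.682) <= 2 / 30),
                label = paste("seed", seed))
  }
})

test_that("simulator stance time is recovered within one frame", {
  s <- simulate_gait(gait_spec(duration_s = 15),
                     noise = gait_noise(jitter_sd = 0, spike_rate = 0), seed = 3)
  a <- analyze_trajectory(s$traj, calib = sim_lateral_calib(s$truth$spec))
  st <- a$temporal$stance_time
  expect_true(all(abs(st[!is.na(st)] - 0.62 * 1.1) <= 1 / 30 + 1e-9))
  # left + right step times reconstruct the stride within a frame
  lt <- a$temporal[a$temporal$side == "left", ]
  rt <- a$temporal[a$temporal$side == "right", ]
  for (i in seq_len(nrow(lt))) {
    j <- which(abs(rt$hs - (lt$hs[i] + lt$step_time[i])) < 1e-6)
    if (length(j) == 1)
      expect_lte(abs(lt$step_time[i] + rt$step_time[j] - lt$stride_time[i]),
                 1 / 30 + 1e-9)
  }
})

test_that("aggregation modes average per subject or pass through", {
  p <- data.frame(subject = c("a", "a", "b"), parameter = "stride_time",
                  value = c(1.0, 1.2, 0.8), side = "left", hs = 1:3)
  pm <- summarize_subject(p, "participants_mean")
  expect_equal(pm$value[pm$subject == "a"], 1.1)
  expect_equal(pm$value[pm$subject == "b"], 0.8)
  expect_identical(summarize_subject(p, "all_step"), p)
  one <- summarize_subject(p[3, ], "participants_mean")
  expect_equal(one$value, 0.8)  # single-cycle subject: identity
})
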