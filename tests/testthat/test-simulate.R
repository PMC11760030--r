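test_that("ground-truth heel strikes are exactly periodic and self-consistent", {
  s <- simulate_gait(gait_spec(stride_time = 1.0, duration_s = 12),
                     noise = gait_noise(jitter_sd = 0, spike_rate = 0), seed = 1)
  hs <- s$truth$events$left$heel_strikes
  expect_gt(length(hs), 9)
  expect_equal(diff(hs), rep(1.0, length(hs) - 1))
  # toe-off at stance_fraction through the stride
  expect_equal(s$truth$events$left$toe_offs[1] - hs[1], 0.62, tolerance = 1e-9)

  # stored ground-truth parameters equal those recomputed by the parameters
  # module from the ground-truth events
  re <- temporal_params(pair_bilateral(s$truth$events$left,
                                       s$truth$events$right,
                                       max_stride_s = 1.5))
  expect_equal(re, s$truth$temporal)
  # and they satisfy the structural invariants exactly
  ok <- !is.na(s$truth$temporal$stance_time)
  expect_identical(s$truth$temporal$stance_time[ok] + s$truth$temporal$swing_time[ok],
                   s$truth$temporal$stride_time[ok])
  expect_equal(s$truth$spatial$gait_speed,
               s$truth$spatial$step_length / s$truth$spatial$step_time)
})

test_that("the generator honours the requested step length", {
  for (target in c(0.45, 0.55, 0.65)) {
    s <- simulate_gait(gait_spec(step_length = target, duration_s = 6),
                       noise = gait_noise(jitter_sd = 0, spike_rate = 0),
                       seed = 1)
    expect_equal(mean(s$truth$spatial$step_length), target, tolerance = 1e-6)
  }
})

test_that("identical seeds give bit-identical outputs", {
  a <- simulate_gait(gait_spec(duration_s = 8), seed = 77)
  b <- simulate_gait(gait_spec(duration_s = 8), seed = 77)
  expect_identical(a$traj$data, b$traj$data)
  expect_identical(a$truth$temporal, b$truth$temporal)
  c <- simulate_gait(gait_spec(duration_s = 8), seed = 78)
  expect_false(identical(a$traj$data, c$traj$data))
})

test_that("impossible waveforms are rejected with the offending location", {
  expect_error(simulate_gait(gait_spec(knee_min_deg = -40, duration_s = 5)),
               "hyperextension")
  expect_error(gait_spec(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_spec(stride_time = -1), "stride_time")
  expect_error(simulate_gait(gait_spec(step_length = 2.5, duration_s = 5)),
               "unreachable")
})

test_that("overground bouts contain the scheduled passes and reversals", {
  s <- simulate_gait(gait_spec(mode = "overground", n_round_trips = 2),
                     noise = gait_noise(jitter_sd = 1, spike_rate = 0), seed = 5)
  expect_equal(nrow(s$truth$passes), 4)
  expect_equal(s$truth$passes$direction,
               c("rightward", "leftward", "rightward", "leftward"))
  clean <- lowpass_zero_lag(extend_edges(despike_and_fill(s$traj)))
  passes <- segment_passes(clean)
  expect_length(passes, 4)
  expect_equal(sapply(passes, `[[`, "direction"), s$truth$passes$direction)
})

test_that("relative-signal period matches ground-truth stride (spectral oracle)", {
  s <- simulate_gait(gait_spec(stride_time = 1.2, duration_s = 18),
                     noise = gait_noise(jitter_sd = 0, spike_rate = 0), seed = 6)
  sig <- relative_ankle_signal(despike_and_fill(s$traj), "left")
  v <- sig$value - mean(sig$value)
  sp <- Mod(fft(v))[2:(length(v) %/% 2)]
  f <- (seq_along(sp)) / (length(v) / 30)
  period <- 1 / f[which.max(sp)]
  expect_equal(period, 1.2, tolerance = 1 / 18)  # one frame over the bout
})

test_that("cohort draws are reproducible and centred on the stated means", {
  co <- simulate_cohort(n_subjects = 24, duration_s = 4, seed = 42)
  strides <- sapply(co, function(s) s$spec$stride_time)
  expect_equal(mean(strides), 1.1, tolerance = 3 * 0.1 / sqrt(24) / 1.1)
  co2 <- simulate_cohort(n_subjects = 24, duration_s = 4, seed = 42)
  expect_identical(lapply(co, function(s) s$cand$lateral$data),
                   lapply(co2, function(s) s$cand$lateral$data))
  expect_error(simulate_cohort(0), "n_subjects")
})

test_that("a noiseless candidate reproduces the reference parameters", {
  co <- simulate_cohort(n_subjects = 1, duration_s = 12,
                        noise = gait_noise(jitter_sd = 0, spike_rate = 0),
                        seed = 13)
  cmp <- compare_systems(co, "lateral")
  tmp <- cmp$report[cmp$report$parameter %in%
                      c("stride_time", "step_time", "stance_time"), ]
  expect_true(all(tmp$mae < 1e-9))
  sl <- cmp$report[cmp$report$parameter == "step_length", ]
  expect_true(all(sl$mae < 0.01 * 0.55))  # spatial within 1%
})

test_that("simulated mean visibility matches the requested profile", {
  prof <- occlusion_profile("treadmill", "lateral")
  s <- simulate_gait(gait_spec(duration_s = 20),
                     noise = gait_noise(visibility = prof), seed = 9)
  expect_equal(mean(traj_vis(s$traj, "right_knee")), prof[["right_knee"]],
               tolerance = 0.05)
  expect_equal(mean(traj_vis(s$traj, "left_knee")), prof[["left_knee"]],
               tolerance = 0.05)
  expect_gt(mean(traj_vis(s$traj, "left_hip")), 0.95)
})
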