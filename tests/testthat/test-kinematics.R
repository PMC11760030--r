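test_that("three-point angle matches an independent acos oracle", {
  expect_equal(three_point_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(three_point_angle(c(-1, 0), c(0, 0), c(1, 0)), 180)  # collinear
  expect_true(is.na(three_point_angle(c(0, 0), c(0, 0), c(1, 0))))

  acos_oracle <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  set.seed(99)
  for (i in 1:200) {
    a <- runif(2, -10, 10); b <- runif(2, -10, 10); c <- runif(2, -10, 10)
    expect_equal(three_point_angle(a, b, c), acos_oracle(a, b, c),
                 tolerance = 1e-9)
  }
})

test_that("the interior angle is invariant under similarity transforms and swaps", {
  set.seed(5)
  rot <- function(p, th) c(cos(th) * p[1] - sin(th) * p[2],
                           sin(th) * p[1] + cos(th) * p[2])
  for (i in 1:50) {
    a <- runif(2); b <- runif(2); c <- runif(2)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 20); d <- runif(2, -5, 5)
    base <- three_point_angle(a, b, c)
    expect_equal(three_point_angle(s * rot(a, th) + d, s * rot(b, th) + d,
                                   s * rot(c, th) + d), base, tolerance = 1e-9)
    expect_equal(three_point_angle(c, b, a), base, tolerance = 1e-12)
  }
})

test_that("a straight standing leg reads zero knee flexion", {
  n <- 30
  pos <- list(left_shoulder = cbind(rep(100, n), 100),
              left_hip = cbind(rep(100, n), 300),
              right_hip = cbind(rep(100, n), 300),
              left_knee = cbind(rep(100, n), 450),
              left_ankle = cbind(rep(100, n), 600),
              left_foot_index = cbind(rep(150, n), 600))
  tr <- make_multi_traj(pos)
  expect_equal(joint_angle_series(tr, "knee", "left")$angle_deg, rep(0, n))
  expect_equal(joint_angle_series(tr, "hip", "left")$angle_deg, rep(0, n))
  # foot perpendicular to shank: neutral ankle
  expect_equal(joint_angle_series(tr, "ankle", "left")$angle_deg, rep(0, n))
  expect_error(joint_angle_series(make_multi_traj(pos[-4]), "knee", "left"),
               "left_knee")
})

test_that("noiseless lateral projection recovers the prescribed waveforms", {
  s <- simulate_gait(gait_spec(duration_s = 12),
                     noise = gait_noise(jitter_sd = 0, spike_rate = 0), seed = 2)
  clean <- despike_and_fill(s$traj)  # no filtering: geometry should be exact
  for (j in c("hip", "knee", "ankle")) {
    est <- joint_angle_series(clean, j, "left")$angle_deg
    gt <- truth_angle_at(s$truth, clean, "left", j)
    expect_lt(angle_agreement(est, gt)$mae, 0.5)
  }
  # near-frontal projection cannot recover sagittal angles as well
  sf <- simulate_gait(gait_spec(duration_s = 12),
                      noise = gait_noise(jitter_sd = 0, spike_rate = 0),
                      view = "near_frontal", seed = 2)
  kn_lat <- angle_agreement(joint_angle_series(clean, "knee", "left")$angle_deg,
                            truth_angle_at(s$truth, clean, "left", "knee"))$mae
  cf <- despike_and_fill(sf$traj)
  kn_fro <- angle_agreement(joint_angle_series(cf, "knee", "left")$angle_deg,
                            truth_angle_at(sf$truth, cf, "left", "knee"))$mae
  expect_gt(kn_fro, kn_lat)
})

test_that("range of motion is max minus min per cycle", {
  fs <- 30; t <- (0:299) / fs
  ev <- gait_events("left", heel_strikes = seq(0.5, 9.5, by = 1))
  flat <- structure(data.frame(frame = 0:299, time_s = t, angle_deg = 5),
                    joint = "knee", side = "left", frame_rate = fs,
                    class = c("joint_angle_series", "data.frame"))
  expect_equal(range_of_motion(flat, ev)$mean, 0)

  sine <- flat; sine$angle_deg <- 20 + 12 * sin(2 * pi * t)
  rom <- range_of_motion(sine, ev)
  expect_equal(rom$mean, 24, tolerance = 0.01)  # 2 x amplitude
  expect_error(range_of_motion(flat, gait_events("left", heel_strikes = 1)),
               "complete cycle")
})

test_that("simulator knee range of motion is recovered within a degree", {
  s <- simulate_gait(gait_spec(duration_s = 15),
                     noise = gait_noise(jitter_sd = 0, spike_rate = 0), seed = 8)
  a <- analyze_trajectory(s$traj, calib = sim_lateral_calib(s$truth$spec))
  rom <- range_of_motion(a$angles$left_knee, a$events$left)
  expect_equal(rom$mean, 55.6, tolerance = 1 / 55.6)  # within 1 degree
})

test_that("angle agreement handles offsets, anticorrelation and mismatches", {
  a <- sin(seq(0, 10, by = 0.1))
  expect_equal(angle_agreement(a, a), list(mae = 0, r = 1, n = length(a)))
  off <- angle_agreement(a, a + 3)
  expect_equal(off$mae, 3)
  expect_equal(off$r, 1)
  expect_equal(angle_agreement(a, -a)$r, -1)
  expect_error(angle_agreement(a, a[-1]), "lengths")
})

test_that("angle error grows monotonically with landmark jitter", {
  maes <- sapply(c(0, 1, 2, 4), function(sig) {
    s <- simulate_gait(gait_spec(duration_s = 12),
                       noise = gait_noise(jitter_sd = sig, spike_rate = 0),
                       seed = 31)
    a <- analyze_trajectory(s$traj, calib = sim_lateral_calib(s$truth$spec))
    angle_agreement(a$angles$left_knee$angle_deg,
                    truth_angle_at(s$truth, a$traj, "left", "knee"))$mae
  })
  expect_true(all(diff(maes) >= 0))
})

test_that("cycle-normalised traces have the requested grid", {
  s <- simulate_gait(gait_spec(duration_s = 12),
                     noise = gait_noise(jitter_sd = 0, spike_rate = 0), seed = 4)
  a <- analyze_trajectory(s$traj, calib = sim_lateral_calib(s$truth$spec))
  m <- cycle_normalize(a$angles$left_knee, a$events$left)
  expect_equal(ncol(m), 101)
  expect_gt(nrow(m), 5)
  expect_false(anyNA(m))
})
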