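test_that("despiking leaves smooth trajectories alone and repairs spikes", {
  # quadratic: constant second difference 2, below threshold 10
  k <- 0:29
  tr <- make_traj(k^2)
  out <- despike_and_fill(tr, preprocess_config(accel_threshold = 10))
  expect_equal(traj_mat(out, "left_ankle")[, 1], k^2)

  # straight line with one +50 px spike
  x <- as.numeric(2 * k + 3); x[15] <- x[15] + 50
  out <- despike_and_fill(make_traj(x), preprocess_config(accel_threshold = 10))
  expect_equal(traj_mat(out, "left_ankle")[, 1], 2 * k + 3, tolerance = 1e-6)
})

test_that("cubic interpolation reproduces a cubic polynomial across a gap", {
  k <- 0:40
  poly <- function(t) 0.02 * t^3 - 0.5 * t^2 + 3 * t + 7
  x <- poly(k)
  x[20:22] <- NA  # 3-frame gap
  out <- despike_and_fill(make_traj(x), preprocess_config(accel_threshold = 1e6))
  expect_equal(traj_mat(out, "left_ankle")[19:24, 1], poly(k[19:24]),
               tolerance = 1e-8)
})

test_that("gaps longer than max_gap_frames stay unfilled; edges never extrapolated", {
  x <- as.numeric(1:60); x[10:25] <- NA; x[c(1, 60)] <- NA
  out <- despike_and_fill(make_traj(x),
                          preprocess_config(accel_threshold = 1e6, max_gap_frames = 10))
  m <- traj_mat(out, "left_ankle")[, 1]
  expect_true(all(is.na(m[10:25])))
  expect_true(is.na(m[1]) && is.na(m[60]))
  held <- extend_edges(out)
  m2 <- traj_mat(held, "left_ankle")[, 1]
  expect_equal(m2[1], m2[2])
  expect_equal(m2[60], m2[59])
})

test_that("landmarks with under 4 valid samples pass through with a warning", {
  x <- c(1, NA, NA, 4, NA, NA, NA, NA, NA, NA)
  expect_warning(out <- despike_and_fill(make_traj(x)), "valid samples")
  expect_equal(traj_mat(out, "left_ankle")[, 1], x)
})

test_that("despike_and_fill is idempotent on its own output", {
  set.seed(42)
  k <- 0:299
  x <- 100 + 50 * sin(2 * pi * k / 33) + rnorm(300, 0, 2)
  x[sample(300, 5)] <- x[sample(300, 5)] + 60  # spikes
  once <- despike_and_fill(make_traj(x))
  twice <- despike_and_fill(once)
  expect_equal(traj_mat(twice, "left_ankle"), traj_mat(once, "left_ankle"))
})

test_that("zero-lag filter matches the analytic two-pass Butterworth gain", {
  fs <- 30; t <- (0:599) / fs
  cfg <- preprocess_config(cutoff_hz = 5, filter_order = 4)
  gain2 <- function(f, fc = 5, n = 4) 1 / (1 + (f / fc)^(2 * n))  # |H|^2

  # constant series is invariant (DC gain 1)
  out <- lowpass_zero_lag(make_traj(rep(7, 600)), cfg)
  expect_equal(traj_mat(out, "left_ankle")[, 1], rep(7, 600), tolerance = 1e-6)

  # 1 Hz passband tone: amplitude preserved within 1%, zero lag
  x1 <- 100 * sin(2 * pi * 1 * t)
  y1 <- traj_mat(lowpass_zero_lag(make_traj(x1), cfg), "left_ankle")[, 1]
  interior <- 60:540
  expect_equal(sd(y1[interior]) / sd(x1[interior]), gain2(1), tolerance = 0.01)
  expect_equal(xcorr_peak_lag(x1[interior], y1[interior]), 0)

  # 10 Hz stopband tone: attenuation ~ 1/(1+(10/5)^8), within 20%
  x10 <- 100 * sin(2 * pi * 10 * t)
  y10 <- traj_mat(lowpass_zero_lag(make_traj(x10), cfg), "left_ankle")[, 1]
  expect_equal(sd(y10[interior]) / sd(x10[interior]), gain2(10), tolerance = 0.2)
})

test_that("filtering commutes with constant offsets and rejects gaps", {
  set.seed(7)
  fs <- 30; t <- (0:299) / fs
  x <- 20 * sin(2 * pi * 1.3 * t) + rnorm(300)
  f <- function(v) traj_mat(lowpass_zero_lag(make_traj(v)), "left_ankle")[, 1]
  expect_equal(f(x + 123.4), f(x) + 123.4, tolerance = 1e-6)
  xg <- x; xg[50] <- NA
  expect_error(lowpass_zero_lag(make_traj(xg)), "gaps")
  expect_error(lowpass_zero_lag(make_traj(x), preprocess_config(cutoff_hz = 20)),
               "Nyquist")
})

test_that("downsampling decimates integer ratios and resamples otherwise", {
  x <- as.numeric(0:239)
  tr <- make_traj(x, fps = 240)
  out <- downsample(tr, 30)
  expect_equal(attr(out, "frame_rate"), 30)
  expect_equal(length(out$frames), 30)
  expect_equal(traj_mat(out, "left_ankle")[, 1], x[seq(1, 240, by = 8)])

  expect_identical(downsample(tr, 240)$data, tr$data)
  expect_error(downsample(tr, 500), "exceeds")

  # 100 -> 30 Hz linear resampling reproduces a line exactly
  line <- 5 + 0.25 * (0:99)
  tr2 <- make_traj(line, fps = 100)
  out2 <- downsample(tr2, 30)
  tt <- out2$frames / 30
  expect_equal(traj_mat(out2, "left_ankle")[, 1], 5 + 0.25 * (tt * 100),
               tolerance = 1e-10)
})

test_that("trim_sync keeps the requested window and re-zeroes the clock", {
  tr <- make_traj(as.numeric(1:300))  # 10 s at 30 fps
  expect_equal(trim_sync(tr, 0, 10)$data, tr$data)
  cut <- trim_sync(tr, 2, 5)
  expect_equal(length(cut$frames), 90)  # 3 s x 30 fps
  expect_equal(cut$frames[1], 0L)
  expect_equal(traj_times(cut)[1], 0)
  expect_error(trim_sync(tr, 5, 2), "start_s")
})

test_that("downsample and trim commute on aligned windows", {
  set.seed(3)
  x <- cumsum(rnorm(240))
  tr <- make_traj(x, fps = 240)
  a <- downsample(trim_sync(tr, 0, 0.5), 30)
  b <- trim_sync(downsample(tr, 30), 0, 0.5)
  expect_equal(traj_mat(a, "left_ankle"), traj_mat(b, "left_ankle"))
})

test_that("pass segmentation splits out-and-back walks by velocity sign", {
  fs <- 30; n <- 360
  ramp <- seq(0, 600, length.out = n)          # monotone rightward
  tri <- c(seq(0, 600, length.out = n / 2),    # out and back
           seq(600, 0, length.out = n / 2))
  base <- function(hx) {
    list(left_hip = cbind(hx, 300), right_hip = cbind(hx, 300),
         left_ankle = cbind(hx, 600), right_ankle = cbind(hx, 600))
  }
  p1 <- segment_passes(make_multi_traj(base(ramp)))
  expect_length(p1, 1)
  expect_equal(p1[[1]]$direction, "rightward")

  p2 <- segment_passes(make_multi_traj(base(tri)))
  expect_length(p2, 2)
  expect_equal(sapply(p2, `[[`, "direction"), c("rightward", "leftward"))
  # pass epochs preserve the original clock
  expect_gt(attr(p2[[2]]$traj, "epoch_s"), 5)
})
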