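# shared test builders

# single-landmark 2D trajectory from coordinate vectors
make_traj <- function(x, y = rep(0, length(x)), fps = 30,
                      landmark = "left_ankle", view = "lateral",
                      visibility = rep(1, length(x))) {
  trajectory_set(data.frame(frame = seq_along(x) - 1L, landmark = landmark,
                            x = x, y = y, visibility = visibility),
                 frame_rate = fps, view = view)
}

# multi-landmark trajectory from a named list of n x 2 matrices
make_multi_traj <- function(pos, fps = 30, view = "lateral",
                            condition = NA_character_) {
  d <- do.call(rbind, lapply(names(pos), function(lm) {
    data.frame(frame = seq_len(nrow(pos[[lm]])) - 1L, landmark = lm,
               x = pos[[lm]][, 1], y = pos[[lm]][, 2], visibility = 1)
  }))
  trajectory_set(d, frame_rate = fps, view = view, condition = condition)
}

# lag (in samples) of the peak cross-correlation between two series
xcorr_peak_lag <- function(a, b, max_lag = 10) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    n <- length(a)
    if (L >= 0) stats::cor(a[1:(n - L)], b[(1 + L):n])
    else stats::cor(a[(1 - L):n], b[1:(n + L)])
  }, double(1))
  lags[which.max(cc)]
}

# exact pixel scale of the simulator's lateral camera
sim_lateral_calib <- function(spec) {
  ppm <- if (spec$mode == "treadmill") 350 else 280
  calibrate_scale(c(0, 0), c(6 * ppm, 0), 6)
}

# interpolate a ground-truth angle trace onto a trajectory's time grid
truth_angle_at <- function(truth, traj, side, joint) {
  stats::approx(truth$angles$time_s,
                truth$angles[[paste(side, joint, sep = "_")]],
                xout = traj_times(traj))$y
}
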