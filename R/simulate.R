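# Synthetic gait generator with exact ground truth. Gait is kinematically
# prescribed (periodic joint waveforms driving a planar lower-limb chain),
# not dynamically simulated: the package tests measurement code, and for that
# the ground truth must be exact.
#
# World frame: X = progression (m), Y = vertical up (m), Z = lateral (m,
# subject's left positive). Cameras project into image pixels with y down.

# canonical waveform shape constants (phase 0 = heel strike). Chosen once so
# that, at the default stance fraction, the forward excursion of the ankle
# relative to the hip peaks at phase ~0 and bottoms out at the
# stance-fraction phase -- the geometry the peak-detection method relies on.
.WAVE <- list(
  hip = list(q1 = 0.00, w2 = 0.00, q2 = 0.10),
  knee = list(q1 = 0.70, w2 = 0.55, q2 = 0.18),
  ankle = list(q1 = 0.45, w2 = 0.45, q2 = 0.00),
  stance_anchor = 0.62  # canonical phase the warp maps stance_fraction onto
)

.wave_shape <- function(p, w) cos(2 * pi * (p - w$q1)) + w$w2 * cos(4 * pi * (p - w$q2))

#' Gait specification for the synthetic generator
#'
#' Defaults describe a typical instrumented-gait bout: 1.1 s stride, 62%
#' stance, 0.55 m steps, 30 s treadmill walking (or two round trips over a
#' 6 m walkway), sampled at 30 fps, with sagittal ranges of motion of about
#' 29 degrees (hip), 55 degrees (knee) and 24 degrees (ankle) -- magnitudes
#' typical of overground walking in older adults with Parkinson's disease.
#'
#' @param stride_time Stride duration in seconds.
#' @param stance_fraction Fraction of the stride spent in stance (0-1).
#' @param step_length Target step length in metres; honoured by scaling the
#'   hip waveform amplitude (see the methods vignette).
#' @param rom_hip,rom_knee,rom_ankle Sagittal ranges of motion in degrees.
#' @param hip_max_deg Peak hip flexion (degrees); `knee_min_deg` minimum knee
#'   flexion.
#' @param knee_min_deg Minimum knee flexion in degrees.
#' @param thigh_m,shank_m,foot_m,trunk_m Segment lengths in metres.
#' @param heel_frac Fraction of the foot length behind the ankle.
#' @param hip_height_m Standing hip height (m); `bounce_m` the vertical hip
#'   oscillation amplitude.
#' @param bounce_m Vertical hip oscillation amplitude in metres.
#' @param pelvis_halfwidth_m,shoulder_halfwidth_m Lateral (Z) offsets.
#' @param mode `"treadmill"` (hip stationary) or `"overground"` (hip advances
#'   at `step_length / step_time`, with direction reversals at the walkway
#'   ends).
#' @param duration_s Bout duration (treadmill); overground duration follows
#'   from the walkway length, speed and `n_round_trips`.
#' @param walkway_m,n_round_trips Overground walkway length and number of
#'   out-and-back round trips.
#' @param turn_s Duration of each direction reversal.
#' @param fps Video frame rate in Hz.
#' @return A list of class `gait_spec`.
#' @export
gait_spec <- function(stride_time = 1.1, stance_fraction = 0.62,
                      step_length = 0.55,
                      rom_hip = 29.2, rom_knee = 55.6, rom_ankle = 24.1,
                      hip_max_deg = 25, knee_min_deg = 3,
                      thigh_m = 0.44, shank_m = 0.43, foot_m = 0.25,
                      heel_frac = 0.25, trunk_m = 0.52,
                      hip_height_m = 0.92, bounce_m = 0.02,
                      pelvis_halfwidth_m = 0.10, shoulder_halfwidth_m = 0.16,
                      mode = c("treadmill", "overground"),
                      duration_s = 30, walkway_m = 6, n_round_trips = 2,
                      turn_s = 1.2, fps = 30) {
  mode <- match.arg(mode)
  if (stride_time <= 0) stop("stride_time must be positive")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must lie strictly between 0 and 1")
  if (step_length <= 0 || fps <= 0 || duration_s <= 0)
    stop("step_length, fps and duration_s must be positive")
  structure(as.list(environment()), class = "gait_spec")
}

#' Noise specification for the synthetic generator
#'
#' Models pose-estimation measurement error: white coordinate jitter,
#' occasional large spikes, and occlusion-driven visibility loss. Visibility
#' is generated as stride-periodic occlusion windows whose duty cycle is set
#' so the per-landmark mean visibility matches `visibility`; samples whose
#' visibility falls below `vis_floor` are emitted as gaps, and occluded but
#' still-visible samples receive extra position noise.
#'
#' @param jitter_sd White landmark jitter SD in pixels.
#' @param spike_rate Probability per landmark-frame of a spike.
#' @param spike_mag Spike magnitude in pixels.
#' @param visibility Optional named vector of per-landmark mean visibilities
#'   in `[0, 1]` (see [occlusion_profile()]); landmarks not named are always
#'   visible. Occluded samples keep (noisy) positions -- pose estimators
#'   guess through occlusions -- with low visibility scores.
#' @param vis_floor Visibility below which a sample becomes a gap (default
#'   0.1; occluded frames scatter isolated dropouts rather than long holes).
#' @param occl_noise_sd Extra position noise SD (px) on occluded samples.
#' @return A list of class `gait_noise`.
#' @export
gait_noise <- function(jitter_sd = 2, spike_rate = 0.002, spike_mag = 40,
                       visibility = NULL, vis_floor = 0.1,
                       occl_noise_sd = 15) {
  stopifnot(jitter_sd >= 0, spike_rate >= 0, spike_rate <= 1, spike_mag >= 0)
  if (!is.null(visibility) &&
      (is.null(names(visibility)) || any(visibility < 0 | visibility > 1)))
    stop("visibility must be a named vector with values in [0, 1]")
  structure(list(jitter_sd = jitter_sd, spike_rate = spike_rate,
                 spike_mag = spike_mag, visibility = visibility,
                 vis_floor = vis_floor, occl_noise_sd = occl_noise_sd),
            class = "gait_noise")
}

#' Empirical per-landmark visibility profiles
#'
#' Mean pose-estimator visibilities characteristic of each filming setup,
#' measured on lateral and near-frontal recordings of treadmill and
#' overground walking: the limb on the far side of a lateral camera is
#' heavily occluded by the body (e.g. far knee ~0.27 on a treadmill filmed
#' from the left), while near-side and frontal landmarks stay mostly visible.
#'
#' @param condition `"treadmill"`, `"overground_forward"` or
#'   `"overground_backward"`.
#' @param view `"lateral"` or `"near_frontal"`.
#' @return Named numeric vector of mean visibilities, one per consumed
#'   landmark, suitable for [gait_noise()]'s `visibility`.
#' @export
occlusion_profile <- function(condition = c("treadmill", "overground_forward",
                                            "overground_backward"),
                              view = c("lateral", "near_frontal")) {
  condition <- match.arg(condition)
  view <- match.arg(view)
  tab <- list(
    treadmill = list(
      near_frontal = c(1.0000, 1.0000, 0.9470, 0.9650, 0.9472, 0.9652,
                       0.7816, 0.7316, 0.9594, 0.9582, 1.0000, 1.0000),
      lateral = c(1.0000, 1.0000, 0.9183, 0.2738, 0.9393, 0.5758,
                  0.8223, 0.6310, 0.9413, 0.7237, 1.0000, 0.9998)),
    overground_forward = list(
      near_frontal = c(0.9997, 0.9993, 0.9878, 0.8507, 0.9859, 0.9053,
                       0.9821, 0.9113, 0.9430, 0.8094, 0.9999, 0.9995),
      lateral = c(0.9983, 0.9994, 0.8689, 0.9842, 0.8912, 0.9797,
                  0.9033, 0.9823, 0.7563, 0.9267, 0.9995, 0.9999)),
    overground_backward = list(
      near_frontal = c(0.9994, 0.9996, 0.9180, 0.9693, 0.9133, 0.9575,
                       0.8620, 0.7999, 0.9296, 0.9513, 0.9998, 1.0000),
      lateral = c(0.9994, 0.9983, 0.9844, 0.8693, 0.9800, 0.8931,
                  0.9826, 0.9048, 0.9278, 0.7616, 0.9999, 0.9995)))
  v <- tab[[condition]][[view]]
  names(v) <- c("left_hip", "right_hip", "left_knee", "right_knee",
                "left_ankle", "right_ankle", "left_heel", "right_heel",
                "left_foot_index", "right_foot_index",
                "left_shoulder", "right_shoulder")
  v
}

# --- waveform machinery ------------------------------------------------------

# piecewise-linear phase warp: real stance fraction -> canonical anchor
.warp_phase <- function(p, sf, anchor = .WAVE$stance_anchor) {
  p <- p %% 1
  ifelse(p <= sf, anchor * p / sf, anchor + (1 - anchor) * (p - sf) / (1 - sf))
}

# build joint waveform functions of real phase; k scales the hip amplitude
.build_waves <- function(spec, k_hip = 1) {
  grid <- seq(0, 1, length.out = 2048 + 1)[-(2048 + 1)]
  rng <- lapply(.WAVE[c("hip", "knee", "ankle")], function(w) {
    s <- .wave_shape(grid, w); c(min(s), max(s))
  })
  norm <- function(joint, p) {
    s <- .wave_shape(p, .WAVE[[joint]])
    (s - rng[[joint]][1]) / (rng[[joint]][2] - rng[[joint]][1])
  }
  hip_mid <- spec$hip_max_deg - spec$rom_hip / 2
  sf <- spec$stance_fraction
  list(
    hip = function(p) hip_mid + k_hip * spec$rom_hip * (norm("hip", .warp_phase(p, sf)) - 0.5),
    knee = function(p) spec$knee_min_deg + spec$rom_knee * norm("knee", .warp_phase(p, sf)),
    ankle = function(p) -spec$rom_ankle / 2 + spec$rom_ankle * norm("ankle", .warp_phase(p, sf))
  )
}

# sagittal limb geometry at real phase p (vectorised); facing = +-1
.limb_sagittal <- function(p, waves, spec, facing = 1) {
  d <- pi / 180
  th <- waves$hip(p); tk <- waves$knee(p); ta <- waves$ankle(p)
  sh <- (th - tk) * d
  knee_x <- facing * spec$thigh_m * sin(th * d)
  knee_y <- -spec$thigh_m * cos(th * d)
  ank_x <- knee_x + facing * spec$shank_m * sin(sh)
  ank_y <- knee_y - spec$shank_m * cos(sh)
  khx <- -facing * sin(sh); khy <- cos(sh)        # unit ankle -> knee
  alpha <- -facing * (90 - ta) * d
  fx <- khx * cos(alpha) - khy * sin(alpha)
  fy <- khx * sin(alpha) + khy * cos(alpha)
  toe <- (1 - spec$heel_frac) * spec$foot_m
  heel <- -spec$heel_frac * spec$foot_m
  list(knee_x = knee_x, knee_y = knee_y, ank_x = ank_x, ank_y = ank_y,
       heel_x = ank_x + heel * fx, heel_y = ank_y + heel * fy,
       toe_x = ank_x + toe * fx, toe_y = ank_y + toe * fy,
       hip_deg = th, knee_deg = tk, ankle_deg = ta)
}

# validate joint waveforms against physiological limits
.check_waves <- function(waves, spec) {
  grid <- seq(0, 1, length.out = 1024 + 1)[-(1024 + 1)]
  tk <- waves$knee(grid); th <- waves$hip(grid)
  bad <- which(tk < -5 | tk > 160 | abs(th) > 70)
  if (length(bad)) {
    fr <- round(grid[bad[1]] * spec$stride_time * spec$fps)
    stop(sprintf(paste0("joint waveforms imply hyperextension beyond limits ",
                        "(knee %.1f deg, hip %.1f deg at phase %.3f, ",
                        "frame ~%d of the first stride)"),
                 tk[bad[1]], th[bad[1]], grid[bad[1]], fr))
  }
  invisible(TRUE)
}

# phase of maximal forward ankle excursion (continuous refinement)
.hs_phase <- function(waves, spec) {
  grid <- seq(0, 1, length.out = 2048 + 1)[-(2048 + 1)]
  ankx <- function(p) .limb_sagittal(p %% 1, waves, spec)$ank_x
  i <- which.max(ankx(grid))
  stats::optimize(ankx, grid[i] + c(-2, 2) / 2048, maximum = TRUE,
                  tol = 1e-10)$maximum %% 1
}

# heel-to-heel step length implied by a hip amplitude scale k
.step_for_k <- function(k, spec) {
  waves <- .build_waves(spec, k)
  pm <- .hs_phase(waves, spec)
  g1 <- .limb_sagittal(pm, waves, spec)
  g2 <- .limb_sagittal((pm + 0.5) %% 1, waves, spec)
  g1$heel_x - g2$heel_x
}

# deterministic simulation state: waves, schedule, ground-truth geometry
.build_sim <- function(spec) {
  f <- function(k) .step_for_k(k, spec) - spec$step_length
  k_hip <- tryCatch(stats::uniroot(f, c(0.15, 2.5), tol = 1e-8)$root,
                    error = function(e)
                      stop("step_length target unreachable with these segment ",
                           "lengths and hip range of motion"))
  waves <- .build_waves(spec, k_hip)
  .check_waves(waves, spec)
  phi_hs <- .hs_phase(waves, spec)

  T <- spec$stride_time
  speed <- 2 * spec$step_length / T
  if (spec$mode == "treadmill") {
    passes <- data.frame(start_s = 0, end_s = spec$duration_s,
                         direction = "rightward", x0 = 0, facing = 1,
                         walked0 = 0)
    duration <- spec$duration_s
  } else {
    pass_dur <- spec$walkway_m / speed
    n_pass <- 2 * spec$n_round_trips
    start <- (seq_len(n_pass) - 1) * (pass_dur + spec$turn_s)
    facing <- rep(c(1, -1), length.out = n_pass)
    passes <- data.frame(start_s = start, end_s = start + pass_dur,
                         direction = ifelse(facing > 0, "rightward", "leftward"),
                         x0 = ifelse(facing > 0, 0, spec$walkway_m),
                         facing = facing,
                         walked0 = (seq_len(n_pass) - 1) * pass_dur)
    duration <- passes$end_s[n_pass]
  }
  list(spec = spec, waves = waves, k_hip = k_hip, phi_hs = phi_hs,
       passes = passes, speed = speed, duration_s = duration)
}

# which pass (row index) each time falls in; 0 = turn interval
.pass_of <- function(sim, t) {
  p <- integer(length(t)) # 0 = turn
  for (i in seq_len(nrow(sim$passes)))
    p[t >= sim$passes$start_s[i] - 1e-9 & t < sim$passes$end_s[i] - 1e-9] <- i
  # times at/after the final pass end belong to it (closed bout end)
  p[t >= sim$passes$end_s[nrow(sim$passes)] - 1e-9] <- nrow(sim$passes)
  p
}

# left-limb phase (strides) and hip X at walking times
.walk_state <- function(sim, t, pass) {
  ps <- sim$passes[pass, , drop = FALSE]
  walked <- ps$walked0 + (t - ps$start_s)
  phase <- walked / sim$spec$stride_time
  x <- if (sim$spec$mode == "treadmill") rep(0, length(t)) else
    ps$x0 + ps$facing * sim$speed * (t - ps$start_s)
  list(phase = phase, x = x, facing = ps$facing)
}

# world positions (X, Y, Z per landmark) at walking times
.kin_at <- function(sim, t, pass = NULL) {
  spec <- sim$spec
  if (is.null(pass)) pass <- .pass_of(sim, t)
  stopifnot(all(pass > 0))
  st <- .walk_state(sim, t, pass)
  hipY <- spec$hip_height_m + spec$bounce_m * sin(4 * pi * st$phase)
  out <- list()
  for (side in c("left", "right")) {
    ph <- st$phase + if (side == "right") 0.5 else 0
    g <- .limb_sagittal(ph, sim$waves, spec, facing = st$facing)
    z <- (if (side == "left") 1 else -1) * spec$pelvis_halfwidth_m
    zs <- (if (side == "left") 1 else -1) * spec$shoulder_halfwidth_m
    out[[.lm_name("hip", side)]] <- cbind(st$x, hipY, z)
    out[[.lm_name("shoulder", side)]] <- cbind(st$x, hipY + spec$trunk_m, zs)
    out[[.lm_name("knee", side)]] <- cbind(st$x + g$knee_x, hipY + g$knee_y, z)
    out[[.lm_name("ankle", side)]] <- cbind(st$x + g$ank_x, hipY + g$ank_y, z)
    out[[.lm_name("heel", side)]] <- cbind(st$x + g$heel_x, hipY + g$heel_y, z)
    out[[.lm_name("foot_index", side)]] <- cbind(st$x + g$toe_x, hipY + g$toe_y, z)
  }
  out
}

# world positions over a frame grid, blending linearly through turn intervals
.sample_motion <- function(sim, times) {
  pass <- .pass_of(sim, times)
  walk <- pass > 0
  out <- NULL
  if (any(walk)) {
    k <- .kin_at(sim, times[walk], pass[walk])
    out <- lapply(k, function(m) {
      full <- matrix(NA_real_, length(times), 3)
      full[walk, ] <- m
      full
    })
  }
  if (any(!walk)) {
    for (i in which(!walk)) {
      prev <- max(which(sim$passes$end_s <= times[i] + 1e-9))
      t0 <- sim$passes$end_s[prev] - 1e-9
      t1 <- sim$passes$start_s[prev + 1]
      a <- .kin_at(sim, t0, prev)
      b <- .kin_at(sim, t1, prev + 1)
      w <- (times[i] - t0) / (t1 - t0)
      w <- w * w * (3 - 2 * w)  # smoothstep
      for (lm in names(a)) out[[lm]][i, ] <- (1 - w) * a[[lm]] + w * b[[lm]]
    }
  }
  out
}

# ground-truth events, parameters and angle traces
.ground_truth <- function(sim) {
  spec <- sim$spec
  T <- spec$stride_time
  ev <- list(left = numeric(0), right = numeric(0))
  for (i in seq_len(nrow(sim$passes))) {
    ps <- sim$passes[i, ]
    for (side in c("left", "right")) {
      off <- if (side == "right") 0.5 else 0
      # phase(t) = (walked0 + t - start)/T ; want phase + off = phi_hs (mod 1)
      m <- seq(floor(ps$walked0 / T) - 2, ceiling((ps$walked0 + ps$end_s - ps$start_s) / T) + 2)
      tt <- ps$start_s + ((sim$phi_hs - off + m) * T - ps$walked0)
      tt <- tt[tt >= ps$start_s - 1e-9 & tt < ps$end_s - 1e-9]
      ev[[side]] <- c(ev[[side]], tt)
    }
  }
  pass_of_t <- function(t) .pass_of(sim, t)
  events <- lapply(c(left = "left", right = "right"), function(sd) {
    hs <- sort(ev[[sd]])
    to <- hs + spec$stance_fraction * T
    to <- to[pass_of_t(to) == pass_of_t(hs)]  # toe-off must stay in its pass
    gait_events(sd, heel_strikes = hs, toe_offs = to, source_view = "truth")
  })
  cycles <- pair_bilateral(events$left, events$right,
                           max_stride_s = 1.5 * T)
  temporal <- temporal_params(cycles)

  # exact step geometry at strike instants
  strikes <- attr(cycles, "strikes")
  spatial <- NULL
  if (nrow(strikes) >= 2) {
    rows <- list()
    for (k in 2:nrow(strikes)) {
      t1 <- strikes$t[k]; t0 <- strikes$t[k - 1]
      if (strikes$side[k] == strikes$side[k - 1]) next
      if (.pass_of(sim, t1) != .pass_of(sim, t0) || .pass_of(sim, t1) == 0) next
      w <- .kin_at(sim, t1)
      len <- abs(w[[.lm_name("heel", strikes$side[k])]][1, 1] -
                   w[[.lm_name("heel", ifelse(strikes$side[k] == "left",
                                              "right", "left"))]][1, 1])
      rows[[length(rows) + 1]] <- data.frame(
        side = strikes$side[k], hs = t1, step_time = t1 - t0,
        step_length = len, gait_speed = len / (t1 - t0))
    }
    if (length(rows)) spatial <- do.call(rbind, rows)
  }

  tt <- seq(0, sim$duration_s, by = 1 / spec$fps)
  tt <- tt[tt < sim$duration_s - 1e-9]
  pass <- .pass_of(sim, tt)
  ang <- data.frame(time_s = tt)
  for (side in c("left", "right")) {
    off <- if (side == "right") 0.5 else 0
    ph <- rep(NA_real_, length(tt))
    st <- .walk_state(sim, tt[pass > 0], pmax(pass[pass > 0], 1))
    ph[pass > 0] <- st$phase + off
    ang[[paste0(side, "_hip")]] <- ifelse(is.na(ph), NA, sim$waves$hip(ph))
    ang[[paste0(side, "_knee")]] <- ifelse(is.na(ph), NA, sim$waves$knee(ph))
    ang[[paste0(side, "_ankle")]] <- ifelse(is.na(ph), NA, sim$waves$ankle(ph))
  }

  structure(list(events = events, cycles = cycles, temporal = temporal,
                 spatial = spatial, angles = ang,
                 passes = sim$passes[c("start_s", "end_s", "direction")],
                 phi_hs = sim$phi_hs, spec = spec, k_hip = sim$k_hip),
            class = "gait_ground_truth")
}

# --- cameras and noise -------------------------------------------------------

.cam_defaults <- function(view, spec) {
  if (view == "lateral") {
    # 1080p smartphone framing: a close treadmill shot vs. a wide walkway shot
    ppm <- if (spec$mode == "treadmill") 350 else 280
    list(ppm = ppm,
         u0 = 960 - ppm * (if (spec$mode == "treadmill") 0 else spec$walkway_m / 2),
         v0 = 540 + ppm * 0.9, cx = 960, cy = 540,
         distortion_k = 0, r_norm_px = 1100)
  } else {
    cam_x <- if (spec$mode == "treadmill") 4 else spec$walkway_m + 1.5
    list(focal_px = 1400, cam_x = cam_x, cam_y = 1.0, u0 = 960, v0 = 540)
  }
}

# world (n x 3 per landmark) -> image pixels per view
.project_view <- function(world, view, cam) {
  if (view == "mocap3d")
    return(lapply(world, function(m) m * 1000))
  if (view == "lateral") {
    out <- lapply(world, function(m) {
      u <- cam$u0 + cam$ppm * m[, 1]
      v <- cam$v0 - cam$ppm * m[, 2]
      if (cam$distortion_k != 0) {
        r2 <- ((u - cam$cx)^2 + (v - cam$cy)^2) / cam$r_norm_px^2
        u <- cam$cx + (u - cam$cx) * (1 + cam$distortion_k * r2)
        v <- cam$cy + (v - cam$cy) * (1 + cam$distortion_k * r2)
      }
      cbind(u, v)
    })
    return(out)
  }
  # near-frontal: perspective with progression along the optical axis
  lapply(world, function(m) {
    depth <- pmax(cam$cam_x - m[, 1], 0.3)
    u <- cam$u0 + cam$focal_px * m[, 3] / depth
    v <- cam$v0 - cam$focal_px * (m[, 2] - cam$cam_y) / depth
    cbind(u, v)
  })
}

# deterministic per-landmark occlusion-window centre phase
.occl_centre <- function(lm) {
  (sum(utf8ToInt(lm) * seq_along(utf8ToInt(lm))) %% 97) / 97
}

# apply jitter, spikes and occlusion-driven visibility to projected pixels
.apply_noise <- function(px, phase, noise) {
  n <- nrow(px[[1]])
  out <- list()
  for (lm in names(px)) {
    m <- px[[lm]] + matrix(stats::rnorm(2 * n, 0, noise$jitter_sd), n, 2)
    spike <- stats::runif(n) < noise$spike_rate
    if (any(spike)) {
      ang <- stats::runif(sum(spike), 0, 2 * pi)
      m[spike, 1] <- m[spike, 1] + noise$spike_mag * cos(ang)
      m[spike, 2] <- m[spike, 2] + noise$spike_mag * sin(ang)
    }
    vis <- stats::runif(n, 0.95, 1)
    target <- noise$visibility[lm]
    if (!is.null(target) && !is.na(target) && target < 0.97) {
      # stride-periodic occlusion windows whose duty cycle reproduces the
      # target mean visibility: occluded ~ U(0.02, 0.40), clear ~ U(0.95, 1)
      q <- min(1, max(0, (0.975 - target) / (0.975 - 0.21)))
      centre <- .occl_centre(lm)
      dist <- abs(((phase - centre + 0.5) %% 1) - 0.5)
      occluded <- !is.na(dist) & dist < q / 2
      vis[occluded] <- stats::runif(sum(occluded), 0.02, 0.40)
      m[occluded, ] <- m[occluded, ] +
        matrix(stats::rnorm(2 * sum(occluded), 0, noise$occl_noise_sd),
               sum(occluded), 2)
    }
    gap <- vis < noise$vis_floor
    m[gap, ] <- NA_real_
    out[[lm]] <- list(pos = m, vis = vis)
  }
  out
}

# --- public generator --------------------------------------------------------

#' Simulate one gait recording with exact ground truth
#'
#' Builds planar lower-limb kinematics from the prescribed joint waveforms
#' and hip translation, projects them into the requested camera view, applies
#' measurement noise and occlusion, and returns the trajectory together with
#' the exact ground truth: heel strikes (the instants of maximal forward
#' ankle excursion relative to the hip), toe-offs (at `stance_fraction`
#' through each stride), per-cycle temporal and spatial parameters, and
#' noiseless joint-angle traces. Deterministic given `seed`.
#'
#' @param spec A [gait_spec()].
#' @param noise A [gait_noise()]; use `gait_noise(jitter_sd = 0,
#'   spike_rate = 0)` for a noiseless recording.
#' @param view `"lateral"`, `"near_frontal"` or `"mocap3d"` (3D marker
#'   positions in millimetres, noiseless, 240 Hz by default).
#' @param seed Integer seed for all randomness.
#' @param fps Frame rate override; defaults to `spec$fps` for video views and
#'   240 Hz for `mocap3d`.
#' @param camera Named list overriding camera defaults (`ppm`, `u0`, `v0`,
#'   `distortion_k`, `r_norm_px` for lateral; `focal_px`, `cam_x`, `cam_y`
#'   for near-frontal).
#' @param subject_id Label stored on the trajectory.
#' @return A list with elements `traj` (a [trajectory_set()]) and `truth`
#'   (class `gait_ground_truth`).
#' @export
simulate_gait <- function(spec = gait_spec(), noise = gait_noise(),
                          view = c("lateral", "near_frontal", "mocap3d"),
                          seed = 1, fps = NULL, camera = list(),
                          subject_id = "S1") {
  view <- match.arg(view)
  sim <- .build_sim(spec)
  truth <- .ground_truth(sim)
  traj <- .render_view(sim, view, noise, seed = seed, fps = fps,
                       camera = camera, subject_id = subject_id)
  list(traj = traj, truth = truth)
}

.render_view <- function(sim, view, noise, seed, fps = NULL, camera = list(),
                         subject_id = "S1") {
  spec <- sim$spec
  if (is.null(fps)) fps <- if (view == "mocap3d") 240 else spec$fps
  tt <- seq(0, sim$duration_s, by = 1 / fps)
  tt <- tt[tt < sim$duration_s - 1e-9]
  world <- .sample_motion(sim, tt)
  cam <- utils::modifyList(.cam_defaults(view, spec), camera)
  px <- .project_view(world, view, cam)
  n <- length(tt)
  condition <- if (spec$mode == "treadmill") "treadmill" else "overground_forward"

  if (view == "mocap3d") {
    d <- do.call(rbind, lapply(names(px), function(lm) {
      data.frame(frame = seq_len(n) - 1L, landmark = lm,
                 x = px[[lm]][, 1], y = px[[lm]][, 2], z = px[[lm]][, 3])
    }))
    return(trajectory_set(d, frame_rate = fps, view = "mocap3d",
                          subject_id = subject_id, condition = condition))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  pass <- .pass_of(sim, tt)
  phase <- rep(NA_real_, n)
  if (any(pass > 0))
    phase[pass > 0] <- .walk_state(sim, tt[pass > 0], pass[pass > 0])$phase
  noisy <- .apply_noise(px, phase, noise)
  d <- do.call(rbind, lapply(names(noisy), function(lm) {
    data.frame(frame = seq_len(n) - 1L, landmark = lm,
               x = noisy[[lm]]$pos[, 1], y = noisy[[lm]]$pos[, 2],
               visibility = noisy[[lm]]$vis)
  }))
  trajectory_set(d, frame_rate = fps, view = view,
                 subject_id = subject_id, condition = condition)
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> %d left / %d right heel strikes, %d cycles\n",
              length(x$events$left$heel_strikes),
              length(x$events$right$heel_strikes), nrow(x$cycles)))
  invisible(x)
}

#' Simulate a cohort of subjects measured by two systems
#'
#' Draws per-subject gait parameters from the stated distributions and emits,
#' for each subject, a noiseless 3D reference recording (240 Hz, the stand-in
#' for marker-based motion capture), one noisy video trajectory per requested
#' view of the same underlying motion on the same clock, and the exact ground
#' truth. All randomness flows through `seed`.
#'
#' @param n_subjects Number of subjects (default 24).
#' @param stride_time_mean,stride_time_sd Stride-time distribution (s);
#'   draws are truncated to `[0.7, 1.6]`.
#' @param step_length_mean,step_length_sd Step-length distribution (m),
#'   truncated to `[0.35, 0.85]`.
#' @param stance_fraction_mean,stance_fraction_sd Stance-fraction
#'   distribution, truncated to `[0.55, 0.70]`.
#' @param views Video views to render (`"lateral"`, `"near_frontal"`).
#' @param noise A [gait_noise()] applied to the video views.
#' @param seed Master seed.
#' @param mode,duration_s,... Passed to [gait_spec()].
#' @return A list of class `gait_cohort`; each element has `subject_id`,
#'   `spec`, `ref` (mocap trajectory), `cand` (named list of video
#'   trajectories), `truth`.
#' @export
simulate_cohort <- function(n_subjects = 24,
                            stride_time_mean = 1.1, stride_time_sd = 0.1,
                            step_length_mean = 0.55, step_length_sd = 0.08,
                            stance_fraction_mean = 0.62,
                            stance_fraction_sd = 0.015,
                            views = "lateral", noise = gait_noise(),
                            seed = 1, mode = "treadmill", duration_s = 30,
                            ...) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (stride_time_sd < 0 || step_length_sd < 0 || stance_fraction_sd < 0)
    stop("distribution SDs must be non-negative")
  set.seed(as.integer(seed))
  rtrunc <- function(n, mean, sd, lo, hi)
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
  stride <- rtrunc(n_subjects, stride_time_mean, stride_time_sd, 0.7, 1.6)
  step <- rtrunc(n_subjects, step_length_mean, step_length_sd, 0.35, 0.85)
  stance <- rtrunc(n_subjects, stance_fraction_mean, stance_fraction_sd, 0.55, 0.70)
  seeds <- sample.int(2^31 - 2, n_subjects)

  out <- lapply(seq_len(n_subjects), function(i) {
    id <- sprintf("S%02d", i)
    spec <- gait_spec(stride_time = stride[i], step_length = step[i],
                      stance_fraction = stance[i], mode = mode,
                      duration_s = duration_s, ...)
    sim <- .build_sim(spec)
    truth <- .ground_truth(sim)
    ref <- .render_view(sim, "mocap3d", noise = NULL, seed = NULL,
                        subject_id = id)
    cand <- lapply(stats::setNames(views, views), function(v)
      .render_view(sim, v, noise, seed = seeds[i] + match(v, views) - 1,
                   subject_id = id))
    list(subject_id = id, spec = spec, ref = ref, cand = cand, truth = truth)
  })
  class(out) <- c("gait_cohort", class(out))
  out
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects, views: %s\n", length(x),
              paste(names(x[[1]]$cand), collapse = ", ")))
  invisible(x)
}
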