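#' Preprocessing configuration
#'
#' Settings for trajectory denoising: the spike criterion (acceleration, i.e.
#' central second difference, in position units per frame squared), the
#' low-pass cutoff and order of the zero-lag Butterworth filter, and the
#' longest gap that cubic interpolation is allowed to bridge.
#'
#' @param accel_threshold Spike threshold in units/frame^2. `NULL` (default)
#'   uses a robust per-landmark threshold of 5 x the median absolute second
#'   difference of that landmark's series.
#' @param cutoff_hz Low-pass cutoff in Hz (default 5).
#' @param filter_order Butterworth order per pass (default 4); the
#'   forward-backward application squares the magnitude response.
#' @param max_gap_frames Gaps longer than this stay unfilled (default 10
#'   frames, about 0.33 s at 30 fps). Use `Inf` to bridge everything.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(accel_threshold = NULL, cutoff_hz = 5,
                              filter_order = 4, max_gap_frames = 10) {
  if (!is.null(accel_threshold) && accel_threshold <= 0)
    stop("accel_threshold must be > 0")
  stopifnot(cutoff_hz > 0, filter_order >= 1, max_gap_frames >= 0)
  structure(list(accel_threshold = accel_threshold, cutoff_hz = cutoff_hz,
                 filter_order = filter_order, max_gap_frames = max_gap_frames),
            class = "preprocess_config")
}

# cubic interpolation of interior gaps; endpoints are never extrapolated.
# FMM end conditions reproduce cubic polynomials exactly.
.fill_gaps <- function(v, max_gap = Inf) {
  ok <- which(!is.na(v))
  if (length(ok) < 4 || length(ok) == length(v)) return(v)
  gaps <- which(is.na(v))
  gaps <- gaps[gaps > min(ok) & gaps < max(ok)]
  if (!length(gaps)) return(v)
  runs <- split(gaps, cumsum(c(1, diff(gaps) != 1)))
  fill <- unlist(runs[vapply(runs, length, integer(1)) <= max_gap],
                 use.names = FALSE)
  if (!length(fill)) return(v)
  v[fill] <- stats::spline(ok, v[ok], xout = fill, method = "fmm")$y
  v
}

#' Despike and gap-fill keypoint trajectories
#'
#' Samples whose acceleration (central second difference of position, taken
#' as the Euclidean magnitude across coordinates) exceeds the threshold are
#' converted to gaps; all interior gaps no longer than
#' `cfg$max_gap_frames` are then filled by cubic interpolation. Endpoints are
#' never extrapolated. Landmarks with fewer than 4 valid samples are passed
#' through unchanged and recorded in the `"warnings"` attribute.
#'
#' @param traj A [trajectory_set()].
#' @param cfg A [preprocess_config()].
#' @return The cleaned trajectory set; gapped-and-filled samples keep their
#'   original visibility, unfillable samples get visibility 0.
#' @export
despike_and_fill <- function(traj, cfg = preprocess_config()) {
  warn <- character(0)
  has_z <- "z" %in% names(traj$data)
  for (lm in traj_landmarks(traj)) {
    m <- traj_mat(traj, lm)
    valid <- rowSums(is.na(m)) == 0
    if (sum(valid) < 4) {
      warn <- c(warn, sprintf("landmark '%s': only %d valid samples, passed through",
                              lm, sum(valid)))
      next
    }
    n <- nrow(m)
    d2 <- m[-c(1, 2), , drop = FALSE] - 2 * m[-c(1, n), , drop = FALSE] +
      m[-c(n - 1, n), , drop = FALSE]
    mag <- c(NA, sqrt(rowSums(d2^2)), NA)  # aligned with samples 2..n-1
    thr <- cfg$accel_threshold
    if (is.null(thr)) thr <- 5 * stats::median(mag, na.rm = TRUE)
    if (!is.finite(thr)) thr <- Inf
    spike <- !is.na(mag) & mag > thr
    m[spike, ] <- NA_real_
    m <- apply(m, 2, .fill_gaps, max_gap = cfg$max_gap_frames)
    traj <- .traj_set(traj, lm, m)
  }
  if (length(warn)) {
    attr(traj, "warnings") <- warn
    warning(paste(warn, collapse = "; "), call. = FALSE)
  }
  traj
}

# reflection-padded forward-backward Butterworth pass over one series
.filtfilt_refl <- function(x, order, cutoff_hz, fs) {
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "low")
  b <- bf$b; a <- bf$a
  npad <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= npad + 1)
    stop(sprintf("series too short for zero-lag filtering (need > %d samples)",
                 npad + 1))
  xx <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  # DC steady-state initial conditions plus reflection padding suppress
  # start-up transients on both passes
  pass <- function(v) {
    k <- length(a) - 1
    as.numeric(signal::filter(b, a, v, init.x = rep(v[1], k),
                              init.y = rep(v[1], k)))
  }
  y <- rev(pass(rev(pass(xx))))
  y[(npad + 1):(npad + n)]
}

#' Zero-lag low-pass Butterworth filtering
#'
#' Applies a low-pass Butterworth filter forward and backward over every
#' coordinate of every landmark, cancelling the phase shift and squaring the
#' magnitude response: the net gain at frequency `f` is
#' `1 / (1 + (f / cutoff)^(2 * order))`. Edge transients are suppressed by
#' odd-reflection padding before each pass. The input must be gap-free (run
#' [despike_and_fill()] first).
#'
#' @inheritParams despike_and_fill
#' @return The filtered trajectory set.
#' @export
lowpass_zero_lag <- function(traj, cfg = preprocess_config()) {
  fs <- attr(traj, "frame_rate")
  if (cfg$cutoff_hz >= fs / 2)
    stop("cutoff_hz must be below the Nyquist frequency (frame_rate / 2)")
  if (anyNA(traj$data$x) || anyNA(traj$data$y))
    stop("trajectory contains gaps; run despike_and_fill() (and extend_edges()) first")
  for (lm in traj_landmarks(traj)) {
    m <- traj_mat(traj, lm)
    m <- apply(m, 2, .filtfilt_refl, order = cfg$filter_order,
               cutoff_hz = cfg$cutoff_hz, fs = fs)
    traj <- .traj_set(traj, lm, m)
  }
  traj
}

#' Hold first/last valid positions over edge gaps
#'
#' [despike_and_fill()] never extrapolates, so a trajectory whose first or
#' last frames are occluded keeps edge gaps. This helper fills them by
#' holding the nearest valid sample, which keeps the series gap-free for
#' filtering without inventing motion. Kept separate (and explicit) from
#' interpolation.
#'
#' @inheritParams despike_and_fill
#' @return The trajectory set with edge gaps held.
#' @export
extend_edges <- function(traj) {
  for (lm in traj_landmarks(traj)) {
    m <- traj_mat(traj, lm)
    ok <- rowSums(is.na(m)) == 0
    if (!any(ok) || all(ok)) next
    first <- which(ok)[1]; last <- max(which(ok))
    if (first > 1) m[seq_len(first - 1), ] <- rep(m[first, ], each = first - 1)
    if (last < nrow(m)) m[(last + 1):nrow(m), ] <-
        rep(m[last, ], each = nrow(m) - last)
    traj <- .traj_set(traj, lm, m)
  }
  traj
}

#' Downsample a trajectory
#'
#' When the source rate is an integer multiple of `target_fps` (e.g. 240 to
#' 30 Hz) every k-th frame is kept, starting at frame 0; otherwise the
#' positions are linearly resampled onto the target time grid.
#'
#' @param traj A [trajectory_set()].
#' @param target_fps Target rate in Hz; must not exceed the source rate.
#' @return A [trajectory_set()] at `target_fps`.
#' @export
downsample <- function(traj, target_fps) {
  fs <- attr(traj, "frame_rate")
  if (target_fps > fs) stop("target_fps exceeds the source frame rate")
  if (target_fps == fs) return(traj)
  if (abs(fs / target_fps - round(fs / target_fps)) < 1e-9) {
    k <- round(fs / target_fps)
    keep <- traj$frames[seq(1, length(traj$frames), by = k)]
    d <- traj$data[traj$data$frame %in% keep, , drop = FALSE]
    d$frame <- match(d$frame, keep) - 1L
    return(.traj_like(traj, d, frame_rate = target_fps))
  }
  t_src <- traj$frames / fs
  t_new <- seq(0, max(t_src), by = 1 / target_fps)
  cols <- intersect(c("x", "y", "z"), names(traj$data))
  out <- do.call(rbind, lapply(traj_landmarks(traj), function(lm) {
    m <- traj_mat(traj, lm)
    v <- traj_vis(traj, lm)
    d <- data.frame(frame = seq_along(t_new) - 1L, landmark = lm)
    for (j in seq_along(cols))
      d[[cols[j]]] <- stats::approx(t_src, m[, j], xout = t_new)$y
    d$visibility <- stats::approx(t_src, v, xout = t_new)$y
    d
  }))
  .traj_like(traj, out, frame_rate = target_fps)
}

#' Trim a trajectory to a synchronisation window
#'
#' Retains frames with time in `[start_s, end_s)` relative to the
#' trajectory's own clock and re-zeroes the frame index and epoch. This is
#' the only place where cross-system clocks are aligned; the sync offsets
#' themselves (e.g. from a recording light) are accepted as inputs.
#'
#' @param traj A [trajectory_set()].
#' @param start_s,end_s Window in seconds, `0 <= start_s < end_s <= duration`.
#' @return The trimmed trajectory set.
#' @export
trim_sync <- function(traj, start_s, end_s) {
  if (start_s < 0 || end_s <= start_s) stop("need 0 <= start_s < end_s")
  fs <- attr(traj, "frame_rate")
  tt <- traj$frames / fs
  keep <- traj$frames[tt >= start_s - 1e-9 & tt < end_s - 1e-9]
  if (!length(keep)) stop("trim window contains no frames")
  d <- traj$data[traj$data$frame %in% keep, , drop = FALSE]
  d$frame <- match(d$frame, keep) - 1L
  .traj_like(traj, d, epoch_s = 0)
}

#' Segment an overground recording into straight walking passes
#'
#' Overground bouts contain direction reversals (out-and-back walking).
#' The hip-centre progression coordinate is low-pass smoothed, and maximal
#' runs of consistent velocity sign lasting at least `min_pass_s` become
#' passes; a guard band is trimmed from both ends of each pass so steps
#' corrupted by the turns are discarded.
#'
#' @param traj A [trajectory_set()] (lateral, near-frontal or mocap view).
#' @param min_pass_s Minimum duration of a sign run to count as a pass.
#' @param guard_s Duration trimmed from each end of every pass.
#' @param smooth_hz Cutoff of the velocity smoothing filter.
#' @return A list of passes; each element has `traj` (a trajectory subset
#'   whose epoch preserves the original clock) and `direction`
#'   (`"rightward"`/`"leftward"`: increasing/decreasing progression
#'   coordinate). Empty list, with a warning, if no run is long enough.
#' @export
segment_passes <- function(traj, min_pass_s = 1, guard_s = 0.5, smooth_hz = 1) {
  fs <- attr(traj, "frame_rate")
  hx <- .hip_centre(traj)[, 1]
  if (anyNA(hx)) hx <- .fill_gaps(hx, Inf)
  if (anyNA(hx)) stop("hip centre has unfillable gaps")
  hx_s <- .filtfilt_refl(hx, 2, smooth_hz, fs)
  v <- c(diff(hx_s), NA)
  sgn <- sign(v)
  sgn[abs(v) < stats::median(abs(v), na.rm = TRUE) * 0.25] <- 0
  r <- rle(sgn[!is.na(sgn)])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 0 & r$lengths >= min_pass_s * fs)
  out <- list()
  for (i in keep) {
    a <- starts[i] + round(guard_s * fs)
    b <- ends[i] - round(guard_s * fs)
    if (b - a < min_pass_s * fs / 2) next
    t0 <- (a - 1) / fs
    t1 <- b / fs
    sub <- trim_sync(traj, t0, t1)
    attr(sub, "epoch_s") <- attr(traj, "epoch_s") + t0
    dir <- if (r$values[i] > 0) "rightward" else "leftward"
    out[[length(out) + 1]] <- list(traj = sub, direction = dir)
  }
  if (!length(out)) warning("no walking pass of at least ", min_pass_s, " s found")
  out
}
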