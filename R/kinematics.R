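# Sagittal-plane joint kinematics from three-landmark triplets.

.JOINT_TRIPLETS <- list(
  hip = c("shoulder", "hip", "knee"),
  knee = c("hip", "knee", "ankle"),
  ankle = c("knee", "ankle", "foot")
)

#' Interior angle at the middle point of a three-point triplet
#'
#' The angle at vertex `b` between rays `b -> a` and `b -> c`, in degrees,
#' computed as `atan2(|cross|, dot)` for numerical stability near 0 and 180
#' degrees. Invariant under rigid rotation, translation and uniform scaling,
#' and under swapping `a` and `c`. Rows may be 2D points or 3D points (for 3D
#' the sagittal projection is taken by the caller). Coincident points give
#' `NA`.
#'
#' @param a,b,c Numeric length-2 vectors, or n x 2 matrices of per-frame
#'   points.
#' @return Interior angle(s) in degrees, in `[0, 180]`.
#' @export
#' @examples
#' three_point_angle(c(0, 1), c(0, 0), c(1, 0))  # 90
three_point_angle <- function(a, b, c) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  a <- as_m(a); b <- as_m(b); c <- as_m(c)
  u <- a - b
  v <- c - b
  dot <- rowSums(u * v)
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  ang <- atan2(abs(cross), dot) * 180 / pi
  bad <- rowSums(u^2) == 0 | rowSums(v^2) == 0
  ang[bad] <- NA_real_
  ang
}

# signed orientation (z of the 2D cross product) of the triplet
.triplet_cross <- function(a, b, c) {
  u <- a - b; v <- c - b
  u[, 1] * v[, 2] - u[, 2] * v[, 1]
}

#' Sagittal joint angle series
#'
#' Per-frame joint angles from the standard landmark triplets: hip from
#' shoulder-hip-knee, knee from hip-knee-ankle, ankle from knee-ankle-foot
#' (the foot point defaults to the toe landmark, configurable to the heel).
#' Hip and knee report flexion as `180 - interior` so full extension reads 0,
#' with the sign taken from the triplet orientation (flexion positive,
#' hyperextension negative, orientation auto-chosen per series so the
#' predominant flexion direction is positive); the ankle reports
#' `90 - interior` so the neutral (foot perpendicular to shank) reads 0 and
#' dorsiflexion is positive. 2D video angles are computed in the image plane;
#' 3D mocap angles in the sagittal (progression-vertical) plane.
#'
#' @param traj A [trajectory_set()].
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param side `"left"` or `"right"`.
#' @param foot_landmark Landmark bound to the ankle triplet's "foot" point:
#'   `"foot_index"` (default) or `"heel"`.
#' @return An object of class `joint_angle_series`: data.frame
#'   `frame, time_s, angle_deg` with attributes `joint`, `side`,
#'   `frame_rate`.
#' @export
joint_angle_series <- function(traj, joint = c("hip", "knee", "ankle"),
                               side = c("left", "right"),
                               foot_landmark = c("foot_index", "heel")) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  foot_landmark <- match.arg(foot_landmark)
  pts <- .JOINT_TRIPLETS[[joint]]
  pts[pts == "foot"] <- foot_landmark
  lms <- .lm_name(pts, side)
  for (lm in lms)
    if (!lm %in% traj_landmarks(traj)) stop("landmark '", lm, "' missing")
  # sagittal plane: image plane for video, progression-vertical for mocap
  m <- lapply(lms, function(lm) traj_mat(traj, lm)[, 1:2, drop = FALSE])
  interior <- three_point_angle(m[[1]], m[[2]], m[[3]])
  if (joint == "ankle") {
    ang <- 90 - interior
  } else {
    mag <- 180 - interior
    cr <- .triplet_cross(m[[1]], m[[2]], m[[3]])
    w <- which(!is.na(mag) & mag > 1)
    orient <- if (length(w)) sign(stats::median(sign(cr[w]))) else 1
    if (orient == 0) orient <- 1
    ang <- mag * sign(cr) * orient
    ang[!is.na(mag) & mag <= 1e-9] <- 0
  }
  out <- data.frame(frame = traj$frames, time_s = traj_times(traj),
                    angle_deg = ang)
  structure(out, joint = joint, side = side,
            frame_rate = attr(traj, "frame_rate"),
            class = c("joint_angle_series", class(out)))
}

#' Range of motion per gait cycle
#'
#' For each cycle (between consecutive ipsilateral heel strikes), the range
#' of motion is the maximum minus the minimum of the joint angle over the
#' cycle, summarised as mean and SD across cycles. Cycles with more than 20%
#' missing samples are skipped.
#'
#' @param series A [joint_angle_series()].
#' @param events A [gait_events()] for the same side and clock.
#' @return A list of class `range_of_motion`: `joint, side, rom` (per-cycle
#'   values), `mean`, `sd`, `n_cycles`.
#' @export
range_of_motion <- function(series, events) {
  hs <- events$heel_strikes
  if (length(hs) < 2) stop("range of motion needs at least one complete cycle")
  tt <- series$time_s
  rom <- c()
  for (k in seq_len(length(hs) - 1)) {
    sel <- tt >= hs[k] & tt < hs[k + 1]
    if (!any(sel)) next
    a <- series$angle_deg[sel]
    if (mean(is.na(a)) > 0.2) next
    rom <- c(rom, max(a, na.rm = TRUE) - min(a, na.rm = TRUE))
  }
  if (!length(rom)) stop("no usable cycle for range of motion")
  structure(list(joint = attr(series, "joint"), side = attr(series, "side"),
                 rom = rom, mean = mean(rom),
                 sd = if (length(rom) > 1) stats::sd(rom) else NA_real_,
                 n_cycles = length(rom)),
            class = "range_of_motion")
}

#' @export
print.range_of_motion <- function(x, ...) {
  cat(sprintf("<range_of_motion> %s %s: %.1f +/- %.1f deg over %d cycles\n",
              x$side, x$joint, x$mean, if (is.na(x$sd)) 0 else x$sd, x$n_cycles))
  invisible(x)
}

#' Agreement between two synchronised angle series
#'
#' Mean absolute error and Pearson correlation between two angle traces of
#' equal length and frame rate (downsample/trim first). Frames missing in
#' either series are dropped pairwise.
#'
#' @param series_a,series_b [joint_angle_series()] objects or numeric
#'   vectors of equal length.
#' @return A list with `mae` (degrees), `r` (Pearson), `n` (frames compared).
#' @export
angle_agreement <- function(series_a, series_b) {
  val <- function(s) if (inherits(s, "joint_angle_series")) s$angle_deg else as.numeric(s)
  a <- val(series_a); b <- val(series_b)
  if (length(a) != length(b))
    stop("angle series have different lengths (", length(a), " vs ", length(b), ")")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 comparable frames")
  a <- a[ok]; b <- b[ok]
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  list(mae = mean(abs(a - b)), r = r, n = sum(ok))
}

#' Cycle-normalised angle traces
#'
#' Resamples each gait cycle of an angle series onto a common 0-100% grid,
#' for ensemble plots of the gait cycle.
#'
#' @param series A [joint_angle_series()].
#' @param events A [gait_events()] for the same side and clock.
#' @param npoints Samples per normalised cycle (default 101).
#' @return A matrix, one row per cycle, `npoints` columns (percent of cycle).
#' @export
cycle_normalize <- function(series, events, npoints = 101) {
  hs <- events$heel_strikes
  if (length(hs) < 2) stop("need at least one complete cycle")
  tt <- series$time_s
  rows <- list()
  for (k in seq_len(length(hs) - 1)) {
    sel <- which(tt >= hs[k] & tt <= hs[k + 1])
    if (length(sel) < 4 || anyNA(series$angle_deg[sel])) next
    rows[[length(rows) + 1]] <- stats::approx(
      (tt[sel] - hs[k]) / (hs[k + 1] - hs[k]), series$angle_deg[sel],
      xout = seq(0, 1, length.out = npoints))$y
  }
  if (!length(rows)) stop("no usable cycle")
  m <- do.call(rbind, rows)
  colnames(m) <- paste0(round(seq(0, 100, length.out = npoints), 1), "%")
  m
}
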