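#' Construct a trajectory set
#'
#' The central container of the package: time-indexed landmark positions with
#' per-sample visibility, at a stated frame rate and camera view.
#'
#' Conventions (fixed once, here): image coordinates are pixels, origin at the
#' top-left, y increasing downward -- the convention of pose-estimator output.
#' 3D motion-capture trajectories are in millimetres with x the progression
#' axis and y the vertical axis. Frame `k` occurs at `epoch_s + k / frame_rate`
#' seconds on the trajectory's own clock; cross-system alignment is done only
#' by [trim_sync()]. Missing positions are explicit gaps (`NA`), never
#' sentinel values; a gap always has visibility < 1.
#'
#' @param data A data.frame with columns `frame` (integer, 0-based),
#'   `landmark`, `x`, `y`, optionally `z` (3D), and optionally `visibility`
#'   in `[0, 1]` (defaults to 1 where a position is present).
#' @param frame_rate Sampling rate in Hz (> 0).
#' @param view One of `"lateral"`, `"near_frontal"`, `"mocap3d"`.
#' @param subject_id,condition Optional labels; `condition` is one of
#'   `"treadmill"`, `"overground_forward"`, `"overground_backward"` or `NA`.
#' @param epoch_s Time of frame 0 on the trajectory's own clock (seconds).
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(data, frame_rate,
                           view = c("lateral", "near_frontal", "mocap3d"),
                           subject_id = NA_character_, condition = NA_character_,
                           epoch_s = 0) {
  view <- match.arg(view)
  stopifnot(is.data.frame(data), frame_rate > 0)
  req <- c("frame", "landmark", "x", "y")
  if (!all(req %in% names(data)))
    stop("`data` must have columns: ", paste(req, collapse = ", "))
  if (!"visibility" %in% names(data)) data$visibility <- 1
  data$landmark <- as.character(data$landmark)
  data$frame <- as.integer(data$frame)

  dup <- duplicated(data[c("frame", "landmark")])
  if (any(dup)) {
    d <- data[which(dup)[1], ]
    stop(sprintf("duplicate (frame, landmark) row: frame %d, landmark '%s'",
                 d$frame, d$landmark))
  }
  data <- data[order(data$landmark, data$frame), , drop = FALSE]

  # rectangularise: every landmark on the full frame grid, gaps where absent
  frames <- sort(unique(data$frame))
  lms <- unique(data$landmark)
  if (nrow(data) < length(frames) * length(lms)) {
    full <- expand.grid(frame = frames, landmark = lms,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data <- merge(full, data, by = c("frame", "landmark"), all.x = TRUE)
    data$visibility[is.na(data$visibility)] <- 0
    data <- data[order(data$landmark, data$frame), , drop = FALSE]
  }

  if (any(data$visibility < 0 | data$visibility > 1, na.rm = TRUE))
    stop("visibility values must lie in [0, 1]")
  gap <- is.na(data$x) | is.na(data$y)
  if ("z" %in% names(data)) gap <- gap | is.na(data$z)
  # a gap never carries visibility 1 (its recorded confidence, if any, stays)
  data$visibility[gap & data$visibility >= 1] <- 0
  data$x[gap] <- NA_real_
  data$y[gap] <- NA_real_
  if ("z" %in% names(data)) data$z[gap] <- NA_real_
  if (is.unsorted(frames, strictly = TRUE)) stop("frame index must be strictly increasing")

  rownames(data) <- NULL
  structure(list(data = data, frames = frames, landmarks = lms),
            frame_rate = frame_rate, view = view, subject_id = subject_id,
            condition = condition, epoch_s = epoch_s,
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d frames x %d landmarks @ %g Hz (%s view)\n",
              length(x$frames), length(x$landmarks),
              attr(x, "frame_rate"), attr(x, "view")))
  cat(sprintf("  time %.3f..%.3f s; subject %s; condition %s\n",
              min(traj_times(x)), max(traj_times(x)),
              attr(x, "subject_id"), attr(x, "condition")))
  gaps <- sum(is.na(x$data$x))
  cat(sprintf("  gaps: %d / %d samples\n", gaps, nrow(x$data)))
  invisible(x)
}

#' Trajectory accessors
#'
#' `traj_times()` returns the time stamp (s) of each frame; `traj_mat()` the
#' position matrix (columns x, y and, for 3D data, z) of one landmark ordered
#' by frame; `traj_vis()` its visibility series; `traj_landmarks()` the
#' landmark names present.
#'
#' @param traj A [trajectory_set()].
#' @param landmark A landmark name present in `traj`.
#' @name trajectory-accessors
#' @export
traj_times <- function(traj) {
  attr(traj, "epoch_s") + traj$frames / attr(traj, "frame_rate")
}

#' @rdname trajectory-accessors
#' @export
traj_landmarks <- function(traj) traj$landmarks

#' @rdname trajectory-accessors
#' @export
traj_mat <- function(traj, landmark) {
  i <- which(traj$data$landmark == landmark)
  if (!length(i)) stop("landmark '", landmark, "' not present in trajectory")
  cols <- intersect(c("x", "y", "z"), names(traj$data))
  m <- as.matrix(traj$data[i, cols, drop = FALSE])
  dimnames(m) <- list(NULL, cols)
  m
}

#' @rdname trajectory-accessors
#' @export
traj_vis <- function(traj, landmark) {
  i <- which(traj$data$landmark == landmark)
  if (!length(i)) stop("landmark '", landmark, "' not present in trajectory")
  traj$data$visibility[i]
}

# replace the position block (and optionally visibility) of one landmark;
# samples left without a position are forced to visibility 0
.traj_set <- function(traj, landmark, mat, vis = NULL) {
  i <- which(traj$data$landmark == landmark)
  stopifnot(length(i) == nrow(mat))
  traj$data$x[i] <- mat[, 1]
  traj$data$y[i] <- mat[, 2]
  if (ncol(mat) >= 3 && "z" %in% names(traj$data)) traj$data$z[i] <- mat[, 3]
  if (!is.null(vis)) traj$data$visibility[i] <- vis
  gap <- rowSums(is.na(mat)) > 0
  traj$data$visibility[i[gap]] <- 0
  traj
}

# rebuild with same metadata, new data
.traj_like <- function(traj, data, frame_rate = attr(traj, "frame_rate"),
                       epoch_s = attr(traj, "epoch_s")) {
  trajectory_set(data, frame_rate = frame_rate, view = attr(traj, "view"),
                 subject_id = attr(traj, "subject_id"),
                 condition = attr(traj, "condition"), epoch_s = epoch_s)
}

# midpoint of the two hip landmarks, as a matrix
.hip_centre <- function(traj) {
  (traj_mat(traj, "left_hip") + traj_mat(traj, "right_hip")) / 2
}
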