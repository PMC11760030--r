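#' Read 2D keypoint trajectories
#'
#' Reads per-frame pose-estimation keypoints from CSV (columns
#' `frame,landmark,x,y,visibility`) or JSON (a list of frames, each a list of
#' `{name, x, y, visibility}` records). Rows are normalised to increasing
#' frame order; samples whose visibility falls below `visibility_floor`
#' become gaps.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param frame_rate Sampling rate in Hz (e.g. 30 for smartphone video).
#' @param view Camera view label, `"lateral"` or `"near_frontal"`.
#' @param visibility_floor Samples with visibility strictly below this value
#'   are converted to gaps. Default 0 keeps every sample.
#' @param subject_id,condition Optional labels stored on the result.
#' @return A [trajectory_set()].
#' @export
read_keypoints <- function(path, frame_rate, view = c("lateral", "near_frontal"),
                           visibility_floor = 0,
                           subject_id = NA_character_, condition = NA_character_) {
  view <- match.arg(view)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    frames <- jsonlite::read_json(path, simplifyVector = FALSE)
    fid <- vapply(frames, function(f) as.integer(f$frame %||% NA_integer_), integer(1))
    if (all(is.na(fid))) fid <- seq_along(frames) - 1L
    if (anyNA(fid) || is.unsorted(fid, strictly = TRUE))
      stop("JSON frames must carry strictly increasing frame numbers")
    data <- do.call(rbind, lapply(seq_along(frames), function(i) {
      recs <- frames[[i]]$landmarks %||% frames[[i]]
      recs <- recs[vapply(recs, is.list, logical(1))]
      data.frame(frame = fid[i],
                 landmark = vapply(recs, function(r) as.character(r$name), character(1)),
                 x = vapply(recs, function(r) .num_or_na(r$x), double(1)),
                 y = vapply(recs, function(r) .num_or_na(r$y), double(1)),
                 visibility = vapply(recs, function(r) .num_or_na(r$visibility, 1), double(1)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "landmark", "x", "y")
    if (!all(need %in% names(data)))
      stop("keypoint CSV must have columns frame,landmark,x,y[,visibility]")
    if (!"visibility" %in% names(data)) data$visibility <- 1
  }
  gap <- !is.na(data$visibility) & data$visibility < visibility_floor
  data$x[gap] <- NA_real_
  data$y[gap] <- NA_real_
  trajectory_set(data, frame_rate = frame_rate, view = view,
                 subject_id = subject_id, condition = condition)
}

.num_or_na <- function(v, default = NA_real_) {
  if (is.null(v) || (is.atomic(v) && length(v) == 1 && is.na(v))) {
    if (is.null(v)) default else NA_real_
  } else as.numeric(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write keypoint trajectories
#'
#' Inverse of [read_keypoints()] / [read_mocap_csv()]. 2D trajectories go to
#' the `frame,landmark,x,y,visibility` CSV dialect or the per-frame JSON
#' dialect; 3D (`mocap3d`) trajectories go to `frame,marker,x,y,z` CSV.
#'
#' @param traj A [trajectory_set()].
#' @param path Output path.
#' @param format `"csv"` or `"json"` (JSON for 2D only).
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(traj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  d <- traj$data
  if (attr(traj, "view") == "mocap3d") {
    out <- data.frame(frame = d$frame, marker = d$landmark,
                      x = d$x, y = d$y, z = d$z)
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  if (format == "csv") {
    utils::write.csv(d[c("frame", "landmark", "x", "y", "visibility")],
                     path, row.names = FALSE, na = "")
  } else {
    frames <- lapply(traj$frames, function(f) {
      di <- d[d$frame == f, , drop = FALSE]
      list(frame = f, landmarks = lapply(seq_len(nrow(di)), function(j) {
        list(name = di$landmark[j], x = di$x[j], y = di$y[j],
             visibility = di$visibility[j])
      }))
    })
    jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

#' Read 3D motion-capture marker trajectories
#'
#' Reads a long-format marker export (`frame,marker,x,y,z`, millimetres,
#' empty cells = gaps) and maps marker names onto the canonical gait landmark
#' vocabulary. The marker map must cover shoulder, hip, knee, ankle, heel and
#' foot tip on both sides.
#'
#' @param path CSV path.
#' @param marker_map Named character vector: `c(marker_name = landmark_name)`,
#'   landmark names as in [gait_landmarks()]. Unmapped markers are dropped.
#' @param frame_rate Sampling rate in Hz (default 240).
#' @param subject_id,condition Optional labels.
#' @return A [trajectory_set()] with `view = "mocap3d"` and visibility 1
#'   wherever a position is present.
#' @export
read_mocap_csv <- function(path, marker_map = NULL, frame_rate = 240,
                           subject_id = NA_character_, condition = NA_character_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("mocap CSV must have columns frame,marker,x,y,z")
  if (is.null(marker_map)) {
    marker_map <- stats::setNames(unique(d$marker), unique(d$marker))
  }
  d <- d[d$marker %in% names(marker_map), , drop = FALSE]
  d$landmark <- unname(marker_map[d$marker])
  missing <- setdiff(gait_landmarks(), unique(d$landmark))
  if (length(missing)) {
    info <- landmark_info(missing)
    stop("marker map leaves body points unmapped: ",
         paste(paste(info$side, sub("foot_index", "foot tip", info$point)),
               collapse = ", "))
  }
  trajectory_set(d[c("frame", "landmark", "x", "y", "z")],
                 frame_rate = frame_rate, view = "mocap3d",
                 subject_id = subject_id, condition = condition)
}

#' Calibrate the pixel-to-metre scale
#'
#' Converts image distances to real-world distances from two marked image
#' points a known distance apart (e.g. floor lines 6 m apart on the walkway).
#'
#' @param point_a_px,point_b_px Numeric length-2 image coordinates (pixels).
#' @param known_distance_m Real-world distance between the points (metres).
#' @return An object of class `scale_calibration` with element
#'   `pixels_per_meter`.
#' @export
#' @examples
#' calibrate_scale(c(0, 0), c(600, 0), 6)  # 100 px/m
calibrate_scale <- function(point_a_px, point_b_px, known_distance_m) {
  stopifnot(length(point_a_px) == 2, length(point_b_px) == 2)
  if (!is.finite(known_distance_m) || known_distance_m <= 0)
    stop("known_distance_m must be positive")
  px <- sqrt(sum((point_a_px - point_b_px)^2))
  if (px == 0) stop("calibration points are coincident")
  structure(list(point_a_px = point_a_px, point_b_px = point_b_px,
                 known_distance_m = known_distance_m,
                 pixels_per_meter = px / known_distance_m),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> %.4f px/m (%.3g m between marks)\n",
              x$pixels_per_meter, x$known_distance_m))
  invisible(x)
}
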