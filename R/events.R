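# Heel-strike / toe-off detection from the ankle (or heel) motion relative to
# the hip centre. Forward excursion of the foot is maximal at heel strike and
# minimal around toe-off, so maxima of the relative progression signal mark
# heel strikes and minima mark toe-offs.

#' Foot-relative-to-hip progression signal
#'
#' Returns the progression-axis coordinate of one side's foot landmark minus
#' the hip centre (midpoint of the two hips), oriented so that forward
#' excursion of the foot is positive. For lateral and mocap views the
#' progression axis is the horizontal coordinate; for near-frontal views,
#' where progression lies along the optical axis, the vertical image
#' coordinate of the heel relative to the hip centre is the detection signal
#' (the nearer/forward foot sits lower in the image).
#'
#' @param traj A gap-free [trajectory_set()].
#' @param side `"left"` or `"right"`.
#' @param landmark Foot landmark to track; defaults to the ankle for
#'   lateral/mocap views and the heel for near-frontal views.
#' @param direction Sign of the progression axis: `"auto"` infers it from the
#'   hip-centre drift (overground), from foot orientation (treadmill lateral),
#'   or from the apparent body-scale change (near-frontal); `+1`/`-1` force it.
#' @return A list of class `gait_signal`: `time_s`, `value`, `frame_rate`,
#'   `side`.
#' @export
relative_ankle_signal <- function(traj, side = c("left", "right"),
                                  landmark = NULL, direction = "auto") {
  side <- match.arg(side)
  view <- attr(traj, "view")
  if (is.null(landmark))
    landmark <- if (view == "near_frontal") "heel" else "ankle"
  lm <- .lm_name(landmark, side)
  for (need in c(lm, "left_hip", "right_hip"))
    if (!need %in% traj_landmarks(traj))
      stop("landmark '", need, "' missing from trajectory")
  hip <- .hip_centre(traj)
  foot <- traj_mat(traj, lm)
  axis <- if (view == "near_frontal") 2L else 1L
  sig <- foot[, axis] - hip[, axis]
  if (anyNA(sig)) stop("signal contains gaps; preprocess the trajectory first")

  s <- if (identical(direction, "auto")) .progression_sign(traj, view) else sign(direction)
  structure(list(time_s = traj_times(traj), value = s * sig,
                 frame_rate = attr(traj, "frame_rate"), side = side),
            class = "gait_signal")
}

# orientation of "forward" in image coordinates
.progression_sign <- function(traj, view) {
  hip <- .hip_centre(traj)
  if (view != "near_frontal") {
    drift <- hip[nrow(hip), 1] - hip[1, 1]
    # a true walking pass translates the body well beyond the foot-swing
    # amplitude; treadmill hip wobble stays far below it
    swing <- 0
    for (sd in c("left", "right")) {
      lm <- .lm_name("ankle", sd)
      if (lm %in% traj_landmarks(traj))
        swing <- max(swing, stats::IQR(traj_mat(traj, lm)[, 1] - hip[, 1],
                                       na.rm = TRUE))
    }
    if (is.finite(drift) && abs(drift) > 2 * max(swing, 1e-9)) return(sign(drift))
    # treadmill: feet point the walking direction
    ori <- 0
    for (sd in c("left", "right")) {
      toe <- .lm_name("foot_index", sd); heel <- .lm_name("heel", sd)
      if (all(c(toe, heel) %in% traj_landmarks(traj)))
        ori <- ori + stats::median(traj_mat(traj, toe)[, 1] -
                                     traj_mat(traj, heel)[, 1], na.rm = TRUE)
    }
    return(if (ori < 0) -1 else 1)
  }
  # near-frontal: apparent inter-hip width grows while approaching the camera,
  # in which case the forward (nearer) foot sits lower in the image (+y)
  w <- abs(traj_mat(traj, "left_hip")[, 1] - traj_mat(traj, "right_hip")[, 1])
  tt <- seq_along(w)
  fit <- stats::coef(stats::lm(w ~ tt))[2]
  if (is.finite(fit) && abs(fit) * length(w) > 0.1 * stats::median(w, na.rm = TRUE))
    return(sign(fit))
  1
}

# local maxima with topographic prominence
.peaks_with_prominence <- function(x) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-1] < 0 & d[-(n - 1)] > 0) + 1L
  # plateau tops: rising into a flat then falling
  flat <- which(d == 0)
  if (length(flat)) {
    for (j in flat) {
      if (j > 1 && d[j - 1] > 0) cand <- c(cand, j + 1L)
    }
    cand <- sort(unique(cand))
  }
  if (!length(cand)) return(data.frame(idx = integer(0), prom = numeric(0)))
  prom <- vapply(cand, function(i) {
    hl <- which(x[seq_len(max(i - 1, 1))] > x[i])
    lb <- if (length(hl)) max(hl) else 0L
    lmin <- min(x[(lb + 1):i])
    hr <- which(x[i:n] > x[i])
    rb <- if (length(hr)) i + min(hr) - 1L else n + 1L
    rmin <- min(x[i:(rb - 1L)])
    x[i] - max(lmin, rmin)
  }, double(1))
  data.frame(idx = cand, prom = prom)
}

# enforce a minimum index distance, keeping the higher peak
.enforce_min_distance <- function(idx, height, min_dist) {
  ord <- order(height, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(idx[kept] - idx[i]) >= min_dist))
      kept <- c(kept, i)
  }
  sort(idx[kept])
}

#' Gait events container
#'
#' @param side `"left"` or `"right"`.
#' @param heel_strikes,toe_offs Strictly increasing event times in seconds.
#' @param source_view View label of the originating trajectory.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(side, heel_strikes = numeric(0), toe_offs = numeric(0),
                        source_view = NA_character_) {
  if (is.unsorted(heel_strikes, strictly = TRUE) ||
      is.unsorted(toe_offs, strictly = TRUE))
    stop("event times must be strictly increasing")
  structure(list(side = side, heel_strikes = heel_strikes,
                 toe_offs = toe_offs, source_view = source_view),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> side %s: %d heel strikes, %d toe-offs\n",
              x$side, length(x$heel_strikes), length(x$toe_offs)))
  invisible(x)
}

#' Detect heel strikes and toe-offs by peak detection
#'
#' Local maxima of the foot-relative-to-hip progression signal are labelled
#' heel strikes and local minima toe-offs. Peaks need a prominence of at
#' least `prominence_frac` of the signal's interquartile range; peaks closer
#' than `min_stride_s` are merged keeping the larger one, and strict
#' alternation (... HS, TO, HS ...) is enforced by dropping the weaker of two
#' same-type neighbours. Events are timestamped at the peak sample, so the
#' timing error is bounded by one frame; optional parabolic sub-frame
#' refinement is available behind `refine`.
#'
#' @param signal A `gait_signal` from [relative_ankle_signal()], or a numeric
#'   vector (then `frame_rate`/`side` must be given and time starts at 0).
#' @param frame_rate,side Used only when `signal` is a bare numeric vector.
#' @param min_stride_s Minimum stride duration; default 0.6 s (cadence
#'   <= 200 steps/min).
#' @param prominence_frac Prominence threshold as a fraction of the signal
#'   IQR (default 0.25).
#' @param refine Parabolic sub-frame peak refinement (default off).
#' @param source_view Stored on the result.
#' @return A [gait_events()] object; empty (with a warning) when fewer than
#'   two strides are found.
#' @export
detect_events <- function(signal, frame_rate = NULL, side = NULL,
                          min_stride_s = 0.6, prominence_frac = 0.25,
                          refine = FALSE, source_view = NA_character_) {
  if (inherits(signal, "gait_signal")) {
    x <- signal$value; tt <- signal$time_s
    frame_rate <- signal$frame_rate
    if (is.null(side)) side <- signal$side
  } else {
    if (is.null(frame_rate) || is.null(side))
      stop("frame_rate and side are required for a bare numeric signal")
    x <- as.numeric(signal)
    tt <- (seq_along(x) - 1) / frame_rate
  }
  if (min_stride_s <= 0) stop("min_stride_s must be positive")
  if (anyNA(x)) stop("signal contains gaps")
  min_prom <- prominence_frac * stats::IQR(x)
  min_dist <- max(1, round(min_stride_s * frame_rate))

  pick <- function(v) {
    p <- .peaks_with_prominence(v)
    p <- p[p$prom >= min_prom & p$prom > 0, , drop = FALSE]
    if (!nrow(p)) return(integer(0))
    .enforce_min_distance(p$idx, v[p$idx], min_dist)
  }
  hs_i <- pick(x)
  to_i <- pick(-x)

  ev <- rbind(
    if (length(hs_i)) data.frame(i = hs_i, type = "HS", h = x[hs_i]),
    if (length(to_i)) data.frame(i = to_i, type = "TO", h = -x[to_i])
  )
  if (is.null(ev) || sum(ev$type == "HS") < 2) {
    warning("fewer than 2 strides detected on side ", side)
    return(gait_events(side, source_view = source_view))
  }
  ev <- ev[order(ev$i), , drop = FALSE]
  # alternation: drop the weaker of two same-type neighbours
  repeat {
    same <- which(diff(match(ev$type, c("HS", "TO"))) == 0)
    if (!length(same)) break
    j <- same[1]
    drop <- if (ev$h[j] >= ev$h[j + 1]) j + 1 else j
    ev <- ev[-drop, , drop = FALSE]
  }
  t_of <- function(rows) {
    if (!nrow(rows)) return(numeric(0))
    if (!refine) return(tt[rows$i])
    vapply(seq_len(nrow(rows)), function(k) {
      i <- rows$i[k]
      if (i <= 1 || i >= length(x)) return(tt[i])
      y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
      den <- y0 - 2 * y1 + y2
      off <- if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
      tt[i] + max(-0.5, min(0.5, off)) / frame_rate
    }, double(1))
  }
  gait_events(side,
              heel_strikes = t_of(ev[ev$type == "HS", , drop = FALSE]),
              toe_offs = t_of(ev[ev$type == "TO", , drop = FALSE]),
              source_view = source_view)
}

#' Merge events from multiple walking passes
#'
#' @param events_list List of [gait_events()] for the same side, on the same
#'   clock (e.g. one per overground pass).
#' @return One [gait_events()] with all events in chronological order.
#' @export
merge_events <- function(events_list) {
  events_list <- Filter(function(e) length(e$heel_strikes) > 0, events_list)
  if (!length(events_list)) stop("no events to merge")
  side <- events_list[[1]]$side
  gait_events(side,
              heel_strikes = sort(unlist(lapply(events_list, `[[`, "heel_strikes"))),
              toe_offs = sort(unlist(lapply(events_list, `[[`, "toe_offs"))),
              source_view = events_list[[1]]$source_view)
}

#' Pair left and right events into validated gait cycles
#'
#' Merges the two sides' heel strikes chronologically and requires strikes to
#' alternate sides; a cycle (two consecutive ipsilateral heel strikes) is
#' kept only when exactly one contralateral strike falls inside it. For each
#' valid cycle the ipsilateral toe-off and the contralateral toe-off that
#' initiates swing of the other limb are attached (NA when absent), which is
#' what the temporal parameters need.
#'
#' @param left,right [gait_events()] of the two sides, same clock.
#' @param max_stride_s Cycles longer than this (e.g. spanning an unfilled
#'   occlusion or a turn) are discarded. Default 2.5 s.
#' @return A data.frame of class `gait_cycles` with one row per valid cycle:
#'   `side, cycle, hs, hs_next, hs_contra, to, to_contra, stride_ok`, plus a
#'   `"strikes"` attribute holding the cleaned bilateral strike sequence.
#' @export
pair_bilateral <- function(left, right, max_stride_s = 2.5) {
  if (!length(left$heel_strikes) || !length(right$heel_strikes))
    stop("both sides must contain heel strikes")
  strikes <- rbind(data.frame(t = left$heel_strikes, side = "left"),
                   data.frame(t = right$heel_strikes, side = "right"))
  strikes <- strikes[order(strikes$t), , drop = FALSE]
  tos <- list(left = left$toe_offs, right = right$toe_offs)

  rows <- list()
  for (sd in c("left", "right")) {
    hs <- if (sd == "left") left$heel_strikes else right$heel_strikes
    contra <- if (sd == "left") "right" else "left"
    hs_c <- if (sd == "left") right$heel_strikes else left$heel_strikes
    if (length(hs) < 2) next
    for (k in seq_len(length(hs) - 1)) {
      h1 <- hs[k]; h2 <- hs[k + 1]
      inside <- hs_c[hs_c > h1 & hs_c < h2]
      if (length(inside) != 1) next            # alternation violated: discard
      if (h2 - h1 > max_stride_s) next
      to_i <- tos[[sd]][tos[[sd]] > h1 & tos[[sd]] < h2]
      to_c <- tos[[contra]][tos[[contra]] > h1 & tos[[contra]] < inside]
      rows[[length(rows) + 1]] <- data.frame(
        side = sd, cycle = k, hs = h1, hs_next = h2, hs_contra = inside,
        to = if (length(to_i) == 1) to_i else NA_real_,
        to_contra = if (length(to_c) >= 1) to_c[1] else NA_real_)
    }
  }
  if (!length(rows)) stop("no valid gait cycle after bilateral pairing")
  out <- do.call(rbind, rows)
  out <- out[order(out$hs, out$side), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strikes") <- strikes
  class(out) <- c("gait_cycles", class(out))
  out
}
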