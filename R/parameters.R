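# Temporospatial gait parameters from validated gait cycles.

#' Temporal gait parameters per cycle
#'
#' From each valid cycle in a [pair_bilateral()] table:
#' stride time = time between consecutive ipsilateral heel strikes;
#' step time = heel strike to next contralateral heel strike;
#' stance time = heel strike to ipsilateral toe-off; swing = stride - stance
#' (exact, by construction); double support = the sum of the two
#' bilateral-contact intervals within the stride (contralateral toe-off minus
#' heel strike, plus ipsilateral toe-off minus contralateral heel strike);
#' cadence = 60 / step time, in steps per minute. A cycle missing its
#' toe-off keeps stride/step/cadence and reports stance, swing and double
#' support as `NA`.
#'
#' @param cycles A `gait_cycles` table from [pair_bilateral()].
#' @return A data.frame with one row per cycle: `side, cycle, hs,
#'   stride_time, step_time, stance_time, swing_time, double_support_time,
#'   cadence`.
#' @export
temporal_params <- function(cycles) {
  stopifnot(inherits(cycles, "gait_cycles"))
  stride <- cycles$hs_next - cycles$hs
  step <- cycles$hs_contra - cycles$hs
  stance <- cycles$to - cycles$hs
  ds <- (cycles$to_contra - cycles$hs) + (cycles$to - cycles$hs_contra)
  out <- data.frame(side = cycles$side, cycle = cycles$cycle, hs = cycles$hs,
                    stride_time = stride, step_time = step,
                    stance_time = stance, swing_time = stride - stance,
                    double_support_time = ds, cadence = 60 / step)
  bad <- !is.na(out$stance_time) & (out$stance_time <= 0 | out$swing_time <= 0)
  out$stance_time[bad] <- NA_real_
  out$swing_time[bad] <- NA_real_
  out$double_support_time[bad] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Spatial gait parameters per step
#'
#' Step length is the instantaneous heel-to-heel separation along the
#' progression axis at each heel strike, converted to metres with the scale
#' calibration (lateral video) or from millimetres (3D mocap); gait speed is
#' step length divided by step time. Spatial parameters are undefined for the
#' near-frontal view, where progression lies along the optical axis.
#'
#' @param traj The (preprocessed) [trajectory_set()] the events came from.
#' @param cycles A `gait_cycles` table from [pair_bilateral()].
#' @param calib A [calibrate_scale()] result; required for video, ignored for
#'   mocap.
#' @param landmark Landmark defining foot placement, `"heel"` (default) or
#'   `"ankle"`.
#' @return A data.frame with one row per step: `side, cycle, hs, step_time,
#'   step_length, gait_speed`. Steps with degenerate (zero) heel separation
#'   are excluded and listed in the `"excluded"` attribute.
#' @export
spatial_params <- function(traj, cycles, calib = NULL, landmark = "heel") {
  view <- attr(traj, "view")
  if (view == "near_frontal")
    stop("spatial parameters undefined for near-frontal view: ",
         "progression lies along the optical axis")
  ppm <- if (view == "mocap3d") 1000 else {
    if (is.null(calib)) stop("a scale calibration is required for video trajectories")
    calib$pixels_per_meter
  }
  tt <- traj_times(traj)
  pos <- list(left = traj_mat(traj, .lm_name(landmark, "left"))[, 1],
              right = traj_mat(traj, .lm_name(landmark, "right"))[, 1])
  at <- function(side, when) {
    i <- which.min(abs(tt - when))
    pos[[side]][i]
  }
  # one step per (heel strike of `side` at hs_contra): contralateral strike
  # inside each cycle, plus the cycle-opening strike itself
  steps <- unique(rbind(
    data.frame(side = ifelse(cycles$side == "left", "right", "left"),
               t = cycles$hs_contra, t_prev = cycles$hs),
    data.frame(side = cycles$side, t = cycles$hs_next, t_prev = cycles$hs_contra)))
  steps <- steps[order(steps$t), , drop = FALSE]
  contra <- ifelse(steps$side == "left", "right", "left")
  sep_px <- vapply(seq_len(nrow(steps)), function(k) {
    abs(at(steps$side[k], steps$t[k]) - at(contra[k], steps$t[k]))
  }, double(1))
  out <- data.frame(side = steps$side, hs = steps$t,
                    step_time = steps$t - steps$t_prev,
                    step_length = sep_px / ppm)
  out$gait_speed <- out$step_length / out$step_time
  degenerate <- !is.na(out$step_length) & out$step_length <= 1e-9
  excluded <- out[degenerate, , drop = FALSE]
  out <- out[!degenerate, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Aggregate per-cycle parameters
#'
#' The two aggregation modes used when comparing measurement systems:
#' `participants_mean` averages each parameter across a subject's cycles
#' first (one value per subject per parameter), `all_step` pools every cycle
#' untouched.
#'
#' @param params A long data.frame with columns `subject`, `parameter`,
#'   `value` (extra columns are preserved in `all_step` mode).
#' @param mode `"participants_mean"` or `"all_step"`.
#' @return A data.frame; in `participants_mean` mode one row per subject per
#'   parameter.
#' @export
summarize_subject <- function(params, mode = c("participants_mean", "all_step")) {
  mode <- match.arg(mode)
  stopifnot(all(c("subject", "parameter", "value") %in% names(params)))
  if (!nrow(params)) stop("no parameter records to summarise")
  if (mode == "all_step") return(params)
  agg <- stats::aggregate(value ~ subject + parameter, data = params,
                          FUN = mean, na.action = stats::na.omit)
  agg[order(agg$subject, agg$parameter), , drop = FALSE]
}

# wide per-cycle tables -> long (subject, side, hs, parameter, value)
.params_long <- function(wide, subject, cols) {
  do.call(rbind, lapply(cols, function(p) {
    data.frame(subject = subject, side = wide$side, hs = wide$hs,
               parameter = p, value = wide[[p]])
  }))
}
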