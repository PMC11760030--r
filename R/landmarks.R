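# Landmark vocabulary. Pose estimators emit a 33-landmark namespace; gait
# analysis consumes the 12 lower-body/trunk points below (6 per side).

.GAIT_POINTS <- c("shoulder", "hip", "knee", "ankle", "heel", "foot_index")

#' Landmark names consumed by the gait pipeline
#'
#' The full 33-landmark namespace of common pose estimators is accepted by the
#' readers; only the twelve landmarks returned here (shoulder, hip, knee,
#' ankle, heel and foot tip, left and right) are consumed downstream. All
#' other names are carried through unchanged and flagged as unconsumed.
#'
#' @param side Optionally restrict to `"left"` or `"right"`.
#' @return Character vector of canonical landmark names, e.g. `"left_ankle"`.
#' @export
#' @examples
#' gait_landmarks()
#' gait_landmarks("left")
gait_landmarks <- function(side = c("both", "left", "right")) {
  side <- match.arg(side)
  sides <- if (side == "both") c("left", "right") else side
  as.vector(t(outer(sides, .GAIT_POINTS, paste, sep = "_")))
}

#' Decompose landmark names into body point and side
#'
#' Every landmark name maps to exactly one (body point, side) pair. Names
#' without a `left_`/`right_` prefix are treated as midline (`"center"`).
#' Unknown names are preserved but flagged via `consumed = FALSE`.
#'
#' @param names Character vector of landmark names.
#' @return A data.frame with columns `name`, `point`, `side`, `consumed`.
#' @export
landmark_info <- function(names) {
  side <- ifelse(grepl("^left_", names), "left",
          ifelse(grepl("^right_", names), "right", "center"))
  point <- sub("^(left|right)_", "", names)
  consumed <- side %in% c("left", "right") & point %in% .GAIT_POINTS
  data.frame(name = names, point = point, side = side, consumed = consumed,
             stringsAsFactors = FALSE)
}

# canonical name for a (point, side) pair
.lm_name <- function(point, side) paste(side, point, sep = "_")
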