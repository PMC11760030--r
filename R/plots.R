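# Plotting helpers for method-comparison figures.

#' Bland-Altman plot
#'
#' Difference (candidate minus reference) against the pairwise mean, with the
#' bias line and the 95% limits of agreement.
#'
#' @param ref,cand Paired numeric vectors.
#' @param title,units Optional labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ref, cand, title = NULL, units = NULL) {
  ba <- bland_altman(ref, cand)
  d <- data.frame(m = (ref + cand) / 2, d = cand - ref)
  ylab <- paste0("candidate - reference", if (!is.null(units)) paste0(" (", units, ")"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "black") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(title = title, x = "mean of methods", y = ylab) +
    ggplot2::theme_minimal()
}

#' Regression plot against the identity line
#'
#' Candidate against reference with the identity line (black) and the fitted
#' least-squares line.
#'
#' @inheritParams plot_bland_altman
#' @return A ggplot object.
#' @export
plot_regression <- function(ref, cand, title = NULL, units = NULL) {
  fr <- fit_identity_regression(ref, cand)
  d <- data.frame(ref = ref, cand = cand)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ref, y = .data$cand)) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_abline(slope = fr$slope, intercept = fr$intercept,
                         colour = "red") +
    ggplot2::labs(title = title,
                  subtitle = sprintf("slope %.4f, r %.4f", fr$slope, fr$pearson_r),
                  x = "reference", y = "candidate") +
    ggplot2::theme_minimal()
}

#' Ensemble plot of cycle-normalised joint angles
#'
#' Mean and SD band of a joint-angle trace across gait cycles, on the 0-100%
#' gait-cycle axis; optionally overlays a second (e.g. reference) series.
#'
#' @param series A [joint_angle_series()].
#' @param events Matching [gait_events()].
#' @param ref_series,ref_events Optional second series to overlay.
#' @return A ggplot object.
#' @export
plot_cycle_angles <- function(series, events, ref_series = NULL,
                              ref_events = NULL) {
  band <- function(s, e, label) {
    m <- cycle_normalize(s, e)
    data.frame(pct = seq(0, 100, length.out = ncol(m)),
               mean = colMeans(m),
               sd = apply(m, 2, stats::sd), which = label)
  }
  d <- band(series, events, "candidate")
  if (!is.null(ref_series))
    d <- rbind(d, band(ref_series, ref_events %||% events, "reference"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$mean,
                                  colour = .data$which, fill = .data$which)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gait cycle (%)", y = "angle (deg)",
                  title = sprintf("%s %s", attr(series, "side"),
                                  attr(series, "joint"))) +
    ggplot2::theme_minimal()
}
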