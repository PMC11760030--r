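# Method-comparison statistics between a candidate (video pose estimation)
# and a reference (motion capture) measurement system.

#' Match gait cycles between two systems
#'
#' Greedy nearest-neighbour, one-to-one matching of heel-strike times from
#' two synchronised systems: pairs are accepted in order of increasing time
#' difference while the difference is at most `tol_s`; unmatched events are
#' dropped.
#'
#' @param ref_times,cand_times Numeric event times (s) on a common clock, or
#'   [gait_events()] objects (their heel strikes are used).
#' @param tol_s Matching tolerance in seconds (default 0.25, below half the
#'   minimum physiological stride).
#' @return A data.frame `ref_idx, cand_idx, dt` (`dt = cand - ref`), ordered
#'   by `ref_idx`. Errors when nothing matches.
#' @export
match_cycles <- function(ref_times, cand_times, tol_s = 0.25) {
  if (inherits(ref_times, "gait_events")) ref_times <- ref_times$heel_strikes
  if (inherits(cand_times, "gait_events")) cand_times <- cand_times$heel_strikes
  if (!length(ref_times) || !length(cand_times)) stop("empty event list")
  dt <- outer(cand_times, ref_times, "-")
  ord <- order(abs(dt))
  used_r <- logical(length(ref_times))
  used_c <- logical(length(cand_times))
  out <- list()
  for (k in ord) {
    if (abs(dt[k]) > tol_s) break
    ci <- (k - 1) %% length(cand_times) + 1
    ri <- (k - 1) %/% length(cand_times) + 1
    if (used_r[ri] || used_c[ci]) next
    used_r[ri] <- TRUE; used_c[ci] <- TRUE
    out[[length(out) + 1]] <- data.frame(ref_idx = ri, cand_idx = ci, dt = dt[k])
  }
  if (!length(out)) stop("no events matched within tol_s = ", tol_s)
  out <- do.call(rbind, out)
  out[order(out$ref_idx), , drop = FALSE]
}

#' Mean absolute error of paired measurements
#'
#' @param ref,cand Paired numeric vectors (reference, candidate).
#' @return A list with `mae` (mean of `|cand - ref|`), `sd` (SD of the
#'   absolute differences) and `n`.
#' @export
mae_stats <- function(ref, cand) {
  stopifnot(length(ref) == length(cand))
  ok <- !is.na(ref) & !is.na(cand)
  d <- abs(cand[ok] - ref[ok])
  if (!length(d)) stop("no complete pairs")
  list(mae = mean(d), sd = if (length(d) > 1) stats::sd(d) else NA_real_,
       n = length(d))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean signed difference (candidate minus reference); the limits
#' of agreement are `bias +/- 1.96` sample (n-1) standard deviations of the
#' differences. See [plot_bland_altman()] for the difference-versus-mean plot
#' with the three reference lines.
#'
#' @inheritParams mae_stats
#' @return A list `bias, loa_low, loa_high, sd, n`.
#' @export
bland_altman <- function(ref, cand) {
  stopifnot(length(ref) == length(cand))
  ok <- !is.na(ref) & !is.na(cand)
  d <- cand[ok] - ref[ok]
  if (length(d) < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  s <- stats::sd(d)
  b <- mean(d)
  list(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s,
       sd = s, n = length(d))
}

#' Least-squares regression of candidate on reference
#'
#' Ordinary least squares fit `candidate = slope * reference + intercept`,
#' with the Pearson correlation reported alongside, so the fit can be judged
#' both against the identity line and as a correlation.
#'
#' @inheritParams mae_stats
#' @return A list `slope, intercept, pearson_r, n`.
#' @export
fit_identity_regression <- function(ref, cand) {
  stopifnot(length(ref) == length(cand))
  ok <- !is.na(ref) & !is.na(cand)
  ref <- ref[ok]; cand <- cand[ok]
  if (length(ref) < 3) stop("regression needs at least 3 pairs")
  if (stats::var(ref) == 0) stop("reference values have zero variance")
  fit <- stats::lm.fit(cbind(1, ref), cand)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       pearson_r = if (stats::var(cand) == 0) NA_real_ else stats::cor(ref, cand),
       n = length(ref))
}

#' Full agreement report between two parameter tables
#'
#' For every parameter shared by the two systems: per-cycle values are paired
#' by matching their heel-strike anchors within `tol_s` (per subject and
#' side), aggregated per `mode` ([summarize_subject()]), and summarised by
#' MAE, Bland-Altman bias/limits of agreement and the regression of candidate
#' on reference. Differences are signed candidate minus reference.
#'
#' @param ref,cand Long parameter tables with columns
#'   `subject, side, hs, parameter, value` (e.g. built by [analyze_trajectory()]).
#' @param mode Aggregation: `"participants_mean"`, `"all_step"`, or both.
#' @param tol_s Cycle-matching tolerance in seconds.
#' @return A data.frame with one row per parameter per mode:
#'   `parameter, mode, n, mae, mae_sd, bias, loa_low, loa_high, slope,
#'   intercept, pearson_r`.
#' @export
agreement_report <- function(ref, cand,
                             mode = c("participants_mean", "all_step"),
                             tol_s = 0.25) {
  mode <- match.arg(mode, several.ok = TRUE)
  need <- c("subject", "side", "hs", "parameter", "value")
  stopifnot(all(need %in% names(ref)), all(need %in% names(cand)))
  subjects <- intersect(unique(ref$subject), unique(cand$subject))
  if (!length(subjects)) stop("the two tables share no subjects")

  pairs <- list()
  for (sub in subjects) for (sd in intersect(unique(ref$side), unique(cand$side))) {
    r <- ref[ref$subject == sub & ref$side == sd, , drop = FALSE]
    cnd <- cand[cand$subject == sub & cand$side == sd, , drop = FALSE]
    if (!nrow(r) || !nrow(cnd)) next
    ra <- sort(unique(r$hs)); ca <- sort(unique(cnd$hs))
    m <- tryCatch(match_cycles(ra, ca, tol_s), error = function(e) NULL)
    if (is.null(m)) next
    for (p in intersect(unique(r$parameter), unique(cnd$parameter))) {
      rv <- r$value[r$parameter == p][match(ra[m$ref_idx], r$hs[r$parameter == p])]
      cv <- cnd$value[cnd$parameter == p][match(ca[m$cand_idx], cnd$hs[cnd$parameter == p])]
      ok <- !is.na(rv) & !is.na(cv)
      if (!any(ok)) next
      pairs[[length(pairs) + 1]] <- data.frame(
        subject = sub, side = sd, parameter = p,
        ref = rv[ok], cand = cv[ok])
    }
  }
  if (!length(pairs)) stop("no matched cycles between the two systems")
  pairs <- do.call(rbind, pairs)

  rows <- list()
  for (md in mode) for (p in unique(pairs$parameter)) {
    pp <- pairs[pairs$parameter == p, , drop = FALSE]
    if (md == "participants_mean") {
      rv <- stats::aggregate(ref ~ subject, pp, mean)$ref
      cv <- stats::aggregate(cand ~ subject, pp, mean)$cand
    } else {
      rv <- pp$ref; cv <- pp$cand
    }
    ms <- mae_stats(rv, cv)
    ba <- if (length(rv) >= 2) bland_altman(rv, cv) else
      list(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
    fr <- tryCatch(fit_identity_regression(rv, cv), error = function(e)
      list(slope = NA_real_, intercept = NA_real_, pearson_r = NA_real_))
    rows[[length(rows) + 1]] <- data.frame(
      parameter = p, mode = md, n = ms$n, mae = ms$mae, mae_sd = ms$sd,
      bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
      slope = fr$slope, intercept = fr$intercept, pearson_r = fr$pearson_r)
  }
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- pairs
  out
}
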