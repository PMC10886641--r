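#' Fit a ROS production rate to a fluorescence trace
#'
#' Ordinary least squares line through the intensity-vs-time curve over the
#' chosen frame window; the slope is the ROS production rate, reported per
#' minute. The default window is the whole recording.
#'
#' @param trace a [fluorescence_trace].
#' @param window integer frame range `c(first, last)` (default: full trace).
#' @return A one-row data.frame of class `rate_result`: `trace_id`, `probe`,
#'   `group`, `slope` (intensity/min), `intercept`, `window_start`,
#'   `window_end`, `r_squared`.
#' @export
fit_rate <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  n <- length(trace$times)
  if (is.null(window)) window <- c(1L, n)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 1 || window[2] > n ||
      window[2] < window[1])
    stop(sprintf("fit window [%d, %d] outside the trace (1..%d)",
                 window[1], window[2], n))
  if (window[2] - window[1] + 1 < 3)
    stop("fit window must contain at least 3 frames")
  idx <- window[1]:window[2]
  t_min <- trace$times[idx] / 60  # minutes
  y <- trace$intensities[idx]
  fit <- stats::lm(y ~ t_min)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  out <- data.frame(trace_id = trace$trace_id, probe = trace$probe,
                    group = trace$group,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    window_start = window[1], window_end = window[2],
                    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("rate_result", "data.frame")
  out
}

#' Normalize per-trace values to the control group
#'
#' Adds `percent_of_control` = 100 * value / mean(control values). All rows
#' whose `group` matches any of `control_group` are pooled before averaging
#' (the two control fibroblast lines are combined), so the control pool
#' averages to exactly 100%. The transformation is idempotent on the
#' percentages and invariant to rescaling every value.
#'
#' @param results a data.frame with a `group` column (e.g. rbind-ed
#'   [fit_rate()] or [measure_potential()] rows).
#' @param control_group character vector of group labels forming the
#'   control pool.
#' @param value name of the value column (default `"slope"`).
#' @return `results` with a `percent_of_control` column appended.
#' @export
normalize_to_control <- function(results, control_group, value = "slope") {
  stopifnot(is.data.frame(results))
  if (!value %in% names(results))
    stop("no column `", value, "` in results")
  if (!"group" %in% names(results))
    stop("results must have a `group` column")
  ctl <- results[[value]][results$group %in% control_group]
  if (length(ctl) == 0)
    stop("control group `", paste(control_group, collapse = "`, `"),
         "` is empty")
  m <- mean(ctl)
  if (m <= 0)
    stop(sprintf("control mean %.4g is not positive; cannot normalize", m))
  results$percent_of_control <- 100 * results[[value]] / m
  results
}

#' Membrane-potential proxy from a TMRM/FCCP trace
#'
#' The potential proxy is the maximal TMRM signal (the plateau reached
#' before FCCP addition) minus the fully depolarized signal after it. Both
#' levels are estimated as `k`-frame means: the post-FCCP level from the
#' final `k` frames (robust to the transient immediately after addition),
#' and the pre-FCCP maximum from the `k` frames just before addition —
#' TMRM loading is monotone, so the underlying signal peaks right before
#' uncoupling, and averaging avoids the upward extreme-value bias a raw
#' per-frame maximum suffers under shot noise. The measure is invariant to
#' a constant offset on the whole trace. A non-positive delta (no drop:
#' mitochondria already uncoupled) is flagged, never silently clipped.
#'
#' @param trace a [fluorescence_trace].
#' @param fccp_frame frame index of FCCP addition.
#' @param k number of frames averaged for each plateau (default 5).
#' @return A one-row data.frame of class `potential_result`: `trace_id`,
#'   `probe`, `group`, `f_max`, `f_post_fccp`, `delta_psi_proxy`, `flagged`.
#' @export
measure_potential <- function(trace, fccp_frame, k = 5) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  n <- length(trace$times)
  fccp_frame <- as.integer(fccp_frame)
  if (fccp_frame < 2 || fccp_frame > n)
    stop(sprintf("`fccp_frame` %d outside the trace (2..%d)", fccp_frame, n))
  if (n - fccp_frame < max(k, 3))
    stop(sprintf(paste0("need at least %d frames after FCCP at frame %d; ",
                        "trace has %d"), max(k, 3), fccp_frame, n))
  pre <- trace$intensities[seq_len(fccp_frame - 1)]
  f_max <- mean(pre[max(1, length(pre) - k + 1):length(pre)])
  f_post <- mean(trace$intensities[(n - k + 1):n])
  delta <- f_max - f_post
  out <- data.frame(trace_id = trace$trace_id, probe = trace$probe,
                    group = trace$group, f_max = f_max, f_post_fccp = f_post,
                    delta_psi_proxy = delta, flagged = delta <= 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("potential_result", "data.frame")
  out
}
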