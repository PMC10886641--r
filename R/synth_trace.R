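#' Specification of a synthetic fluorescence time series
#'
#' Describes either a linear-drift trace (ROS probes: intensity rises
#' linearly while the probe oxidizes) or a plateau-then-drop trace (TMRM:
#' stable potential-dependent signal quenched by FCCP at a known frame).
#' Frame interval defaults to 5 s (1 frame / 5 s recording).
#'
#' @param n_frames number of frames (>= 3).
#' @param dt frame interval in seconds (default 5).
#' @param baseline starting intensity.
#' @param slope intensity change per frame (0 for plateau traces).
#' @param fccp_frame frame index at which FCCP is added (NULL = never).
#' @param fccp_drop intensity drop applied from `fccp_frame` on.
#' @param noise_sd additive Gaussian noise sd (>= 0).
#' @param seed integer seed; identical specs give identical traces.
#' @return A validated object of class `trace_spec`.
#' @export
trace_spec <- function(n_frames = 60, dt = 5, baseline = 100, slope = 0,
                       fccp_frame = NULL, fccp_drop = 0, noise_sd = 0,
                       seed = NULL) {
  stopifnot(n_frames >= 3, dt > 0, noise_sd >= 0)
  if (!is.null(fccp_frame)) {
    if (fccp_frame < 1 || fccp_frame >= n_frames)
      stop("`fccp_frame` must lie within the trace (1 <= f < n_frames)")
  }
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 baseline = baseline, slope = slope,
                 fccp_frame = if (is.null(fccp_frame)) NULL
                              else as.integer(fccp_frame),
                 fccp_drop = fccp_drop, noise_sd = noise_sd, seed = seed),
            class = "trace_spec")
}

#' Generate a synthetic fluorescence trace
#'
#' intensity(frame) = baseline + slope * (frame - 1) + noise, with a step
#' drop of `fccp_drop` from `fccp_frame` onwards when present.
#'
#' @param spec a [trace_spec()].
#' @param trace_id identifier stored in the trace.
#' @param probe probe label (`DCF`, `MitoSOX`, `CM-H2XRos`, `TMRM`, ...).
#' @param group group label (cell line / condition).
#' @return A [fluorescence_trace].
#' @export
generate_trace <- function(spec, trace_id = "trace", probe = "DCF",
                           group = "Control") {
  stopifnot(inherits(spec, "trace_spec"))
  with_local_seed(spec$seed, {
    f <- seq_len(spec$n_frames)
    y <- spec$baseline + spec$slope * (f - 1)
    if (!is.null(spec$fccp_frame))
      y[f >= spec$fccp_frame] <- y[f >= spec$fccp_frame] - spec$fccp_drop
    if (spec$noise_sd > 0)
      y <- y + stats::rnorm(spec$n_frames, sd = spec$noise_sd)
    fluorescence_trace(times = (f - 1) * spec$dt, intensities = y,
                       trace_id = trace_id, probe = probe, group = group)
  })
}

#' Fluorescence time series
#'
#' @param times sample times in seconds, strictly increasing, >= 3 samples.
#' @param intensities finite fluorescence intensities, same length.
#' @param trace_id identifier.
#' @param probe probe label.
#' @param group group label (cell line + condition).
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, intensities, trace_id = "trace",
                               probe = "DCF", group = "Control") {
  if (length(times) < 3) stop("a trace needs at least 3 samples")
  if (length(times) != length(intensities))
    stop("`times` and `intensities` must have equal length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  structure(list(trace_id = trace_id, probe = probe, group = group,
                 times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s (%s, %s): %d frames, %.3g s/frame\n",
              x$trace_id, x$probe, x$group, length(x$times),
              stats::median(diff(x$times))))
  invisible(x)
}

#' Write a set of traces to CSV
#'
#' Long format: trace_id, probe, group, frame, time_s, intensity.
#'
#' @param traces list of [fluorescence_trace] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id, probe = tr$probe, group = tr$group,
               frame = seq_along(tr$times), time_s = tr$times,
               intensity = tr$intensities)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from a long-format CSV
#'
#' Expects columns trace_id, probe, group, frame, time_s, intensity.
#'
#' @param path CSV path.
#' @return A list of [fluorescence_trace] objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "probe", "group", "frame", "time_s", "intensity")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$frame), ]
    fluorescence_trace(d$time_s, d$intensity, trace_id = d$trace_id[1],
                       probe = d$probe[1], group = d$group[1])
  })
}
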