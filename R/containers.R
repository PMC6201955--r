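#' Fluorescence trace
#'
#' One neuron's sampled optical signal for one sweep. Sampling is uniform at
#' `frame_rate` frames per second starting at `t0`.
#'
#' @param samples Numeric vector of fluorescence values.
#' @param frame_rate Sampling rate, frames/s (250 for the MiCam-style
#'   acquisition emulated here).
#' @param neuron_id Identifier of the soma the trace was extracted from.
#' @param sweep_id Identifier of the sweep (trial).
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `fl_trace`.
#' @export
fl_trace <- function(samples, frame_rate = 250, neuron_id = "n1",
                     sweep_id = "s1", t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 2L)
    abort_bad_arg("samples", "must be a numeric vector of length >= 2")
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(t0, "t0")
  structure(list(
    neuron_id = as.character(neuron_id),
    sweep_id = as.character(sweep_id),
    samples = as.numeric(samples),
    frame_rate = frame_rate,
    t0 = t0
  ), class = "fl_trace")
}

#' Time axis of a fluorescence trace
#' @param trace An [fl_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  check_trace(trace)
  trace$t0 + (seq_along(trace$samples) - 1) / trace$frame_rate
}

check_trace <- function(x, arg = "trace") {
  if (!inherits(x, "fl_trace")) abort_bad_arg(arg, "must be an fl_trace")
  invisible(x)
}

#' @export
print.fl_trace <- function(x, ...) {
  cat(sprintf("<fl_trace> %s/%s: %d samples @ %g fps (%.3g s)\n",
              x$neuron_id, x$sweep_id, length(x$samples), x$frame_rate,
              length(x$samples) / x$frame_rate))
  invisible(x)
}

#' Spike train
#'
#' Ordered spike times for a single unit. Times must be strictly increasing.
#'
#' @param times Numeric vector of spike times, seconds.
#' @param unit_id Unit identifier (a CoG soma, an intracellular reference
#'   electrode, or a motor unit such as `"PD"`).
#' @param source One of `"optical"`, `"intracellular"`, `"extracellular"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times = numeric(0), unit_id = "u1",
                        source = c("optical", "intracellular",
                                   "extracellular")) {
  source <- match.arg(source)
  if (length(times) && (!is.numeric(times) || any(!is.finite(times))))
    abort_bad_arg("times", "must be finite numeric spike times")
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    abort_bad_arg("times", "must be strictly increasing")
  structure(list(unit_id = as.character(unit_id), times = times,
                 source = source),
            class = "spike_train")
}

check_spike_train <- function(x, arg = "train") {
  if (!inherits(x, "spike_train")) abort_bad_arg(arg, "must be a spike_train")
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes", x$unit_id, x$source,
              length(x$times)))
  if (length(x$times))
    cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Count spikes in a half-open window
#'
#' @param train A [spike_train()].
#' @param window Numeric `c(start, end)`; spikes in `[start, end)` count.
#' @return Integer spike count.
#' @export
spike_count <- function(train, window) {
  check_spike_train(train)
  check_interval(window, "window")
  sum(train$times >= window[1] & train$times < window[2])
}
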