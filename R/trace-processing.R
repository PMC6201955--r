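#' Spike-detection parameters
#'
#' Parameters for converting a drift-removed, high-pass-filtered
#' fluorescence trace into spike times. The threshold follows the robust
#' median-based noise estimate common in extracellular spike detection:
#' `threshold = threshold_k * median(|x|) / 0.6745`.
#'
#' @param poly_degree Degree of the polynomial drift fit.
#' @param threshold_k Threshold multiplier on the robust noise SD.
#' @param highpass_cutoffs Candidate high-pass cutoffs (Hz) for the
#'   per-neuron filter tuning; all must lie below the Nyquist frequency of
#'   the trace they are applied to.
#' @param refractory Minimum spacing between detected spikes, seconds
#'   (default one frame at 250 frames/s, guarding against double counts of
#'   undersampled optical spikes).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(poly_degree = 6, threshold_k = 4,
                             highpass_cutoffs = c(5, 10, 20, 40),
                             refractory = 0.004) {
  check_number(poly_degree, "poly_degree", lower = 0)
  check_number(threshold_k, "threshold_k", lower = 1e-12)
  if (!length(highpass_cutoffs) || any(highpass_cutoffs <= 0))
    abort_bad_arg("highpass_cutoffs", "must be positive frequencies")
  check_number(refractory, "refractory", lower = 0)
  structure(list(poly_degree = poly_degree, threshold_k = threshold_k,
                 highpass_cutoffs = as.numeric(highpass_cutoffs),
                 refractory = refractory),
            class = "detection_params")
}

#' Remove slow baseline drift by polynomial fit
#'
#' Subtracts the least-squares polynomial fit of the given degree (degree 6
#' by default, matching the drift model of the acquisition) from the trace.
#' The output has mean ~0 and the operation is idempotent.
#'
#' @param trace An [fl_trace()].
#' @param degree Polynomial degree.
#' @return The drift-removed [fl_trace()].
#' @export
remove_drift <- function(trace, degree = 6) {
  check_trace(trace)
  check_number(degree, "degree", lower = 0)
  n <- length(trace$samples)
  if (n <= degree + 1)
    abort_bad_arg("trace", "too short for the requested polynomial degree")
  t <- trace_times(trace)
  if (diff(range(t)) < 1e-12)
    abort_bad_arg("trace", "degenerate (constant) time axis")
  fit <- if (degree == 0) {
    rep(mean(trace$samples), n)
  } else {
    stats::lm.fit(cbind(1, stats::poly(t, degree)), trace$samples)$fitted.values
  }
  trace$samples <- trace$samples - as.numeric(fit)
  trace
}

# zero-phase 2nd-order Butterworth high-pass
highpass_filter <- function(x, cutoff, frame_rate) {
  nyq <- frame_rate / 2
  if (cutoff >= nyq)
    abort_bad_arg("cutoff", "must be below the Nyquist frequency")
  bf <- signal::butter(2, cutoff / nyq, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Apply a zero-phase high-pass filter to a trace
#'
#' Second-order Butterworth applied forward-backward, separating fast
#' spike transients from slower membrane-potential changes.
#'
#' @param trace An [fl_trace()] (drift already removed).
#' @param cutoff High-pass cutoff, Hz.
#' @return The filtered [fl_trace()].
#' @export
highpass_trace <- function(trace, cutoff) {
  check_trace(trace)
  check_number(cutoff, "cutoff", lower = 1e-9)
  trace$samples <- highpass_filter(trace$samples, cutoff, trace$frame_rate)
  trace
}

#' Tune the per-neuron high-pass cutoff
#'
#' Spike amplitudes differ between somata, so the high-pass cutoff is
#' chosen per neuron: for each candidate cutoff the trace is split into a
#' fast band (high-passed) and a slow residual (trace minus fast band), and
#' the cutoff maximizing
#' `max(|fast band|) - max(|slow residual|)` is selected — the cutoff that
#' best separates fast spike transients from slow membrane-potential sway.
#' Ties resolve to the lowest candidate.
#'
#' @param trace An [fl_trace()], drift removed.
#' @param params A [detection_params()] carrying the candidate cutoffs.
#' @return The selected cutoff, Hz.
#' @export
tune_highpass <- function(trace, params = detection_params()) {
  check_trace(trace)
  if (!inherits(params, "detection_params"))
    abort_bad_arg("params", "must be a detection_params")
  cands <- params$highpass_cutoffs
  if (!length(cands)) abort_bad_arg("params", "empty candidate cutoff list")
  if (length(cands) == 1L) return(cands)
  score <- vapply(sort(cands), function(cutoff) {
    fast <- highpass_filter(trace$samples, cutoff, trace$frame_rate)
    slow <- trace$samples - fast
    max(abs(fast)) - max(abs(slow))
  }, numeric(1))
  sort(cands)[which.max(score)]  # which.max takes the first (lowest) on ties
}

#' Detect spikes by median-based thresholding
#'
#' Sets the threshold at `threshold_k * median(|x|) / 0.6745` (the robust
#' SD estimate of the background) and reports spikes at the
#' above-threshold local maxima of the trace, so that transients whose
#' tails overlap are still resolved. The refractory spacing is enforced
#' greedily from the largest peak down. An all-constant trace yields an
#' empty train. Reported times are peak-sample times; the optical
#' transient peaks a kernel-dependent 2-3 ms after the action potential,
#' so validation against electrode spike times should allow for that
#' systematic latency (see [kernel_peak_delay()]).
#'
#' @param trace An [fl_trace()], drift-removed and high-pass filtered.
#' @param params A [detection_params()].
#' @return A [spike_train()] with `source = "optical"`.
#' @export
detect_spikes <- function(trace, params = detection_params()) {
  check_trace(trace)
  if (!inherits(params, "detection_params"))
    abort_bad_arg("params", "must be a detection_params")
  x <- trace$samples
  thr <- params$threshold_k * stats::median(abs(x)) / 0.6745
  n <- length(x)
  is_peak <- x > thr &
    x >= c(-Inf, x[-n]) &   # >= left neighbour (plateau start wins)
    x > c(x[-1], -Inf)      # > right neighbour
  peaks <- which(is_peak)
  if (!length(peaks))
    return(spike_train(numeric(0), trace$neuron_id, "optical"))
  t <- trace_times(trace)
  ord <- peaks[order(x[peaks], decreasing = TRUE)]
  accepted <- numeric(0)
  for (i in ord) {
    if (!length(accepted) ||
        min(abs(t[i] - accepted)) >= params$refractory)
      accepted <- c(accepted, t[i])
  }
  spike_train(sort(accepted), trace$neuron_id, "optical")
}

#' Full optical spike-detection chain
#'
#' Convenience wrapper: drift removal, per-neuron high-pass tuning and
#' filtering, then median-threshold detection.
#'
#' @inheritParams detect_spikes
#' @return A [spike_train()].
#' @export
process_trace <- function(trace, params = detection_params()) {
  d <- remove_drift(trace, params$poly_degree)
  cutoff <- tune_highpass(d, params)
  detect_spikes(highpass_trace(d, cutoff), params)
}

#' Match an optical spike train against a reference
#'
#' Greedy nearest-neighbour pairing within a latency tolerance, mirroring
#' spike-to-spike latency validation of optical detection against a
#' simultaneous intracellular recording. Unpaired test spikes are
#' overdetections, unpaired reference spikes underdetections; their sum is
#' the misdetection count.
#'
#' @param test The [spike_train()] under scrutiny (e.g. optical).
#' @param reference The ground-truth or reference [spike_train()].
#' @param tolerance Maximum |latency| for a valid pair, seconds.
#' @return A list of class `match_report`: `n_matched`, `over`, `under`,
#'   `misdetections`, `latencies` (test minus reference, seconds) and the
#'   paired index matrix `pairs`.
#' @export
match_spike_trains <- function(test, reference, tolerance = 0.004) {
  check_spike_train(test, "test")
  check_spike_train(reference, "reference")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    abort_bad_arg("tolerance", "must be a single non-negative number")
  nt <- length(test$times); nr <- length(reference$times)
  pairs <- NULL
  if (nt && nr) {
    d <- abs(outer(test$times, reference$times, `-`))
    cand <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_t <- logical(nt); used_r <- logical(nr)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_t[i] && !used_r[j]) {
          keep[k] <- TRUE
          used_t[i] <- TRUE; used_r[j] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  over <- nt - n_matched
  under <- nr - n_matched
  latencies <- if (n_matched)
    test$times[pairs[, 1]] - reference$times[pairs[, 2]] else numeric(0)
  structure(list(n_matched = n_matched, over = over, under = under,
                 misdetections = over + under, latencies = latencies,
                 pairs = pairs),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d matched, %d over, %d under (%d misdetected)\n",
              x$n_matched, x$over, x$under, x$misdetections))
  invisible(x)
}

#' Mean firing frequency over a window
#'
#' Number of spikes in the half-open window `[start, end)` divided by the
#' window duration.
#'
#' @param train A [spike_train()].
#' @param window Numeric `c(start, end)`, seconds.
#' @return Firing frequency, Hz.
#' @export
firing_frequency <- function(train, window) {
  check_spike_train(train)
  check_interval(window, "window")
  spike_count(train, window) / (window[2] - window[1])
}
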