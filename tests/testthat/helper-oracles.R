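# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force, not through the
# package's own code paths.

# Pearson coherence by direct double-loop evaluation of the centered
# cross-product formula.
pearson_formula_oracle <- function(V) {
  K <- ncol(V)
  rho <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      vi <- V[, i] - mean(V[, i])
      vj <- V[, j] - mean(V[, j])
      rho[i, j] <- sum(vi * vj) / sqrt(sum(vi^2) * sum(vj^2))
    }
  }
  rho
}

# Global efficiency by Floyd-Warshall all-pairs shortest paths.
fw_efficiency_oracle <- function(A) {
  K <- nrow(A)
  D <- matrix(Inf, K, K)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(K)) {
    for (i in seq_len(K)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (K * (K - 1))
}

# Erdos-Renyi adjacency fixture.
random_adjacency <- function(K, p) {
  A <- matrix(0, K, K)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < p)
  A + t(A)
}

# Flat synthetic trace with kernels pasted at known times.
trace_with_kernels <- function(times, noise = trace_noise_spec(
                                 drift_amplitude = 0,
                                 gaussian_noise_sd = 0),
                               sweep_length = noise$sweep_length) {
  t_grid <- (seq_len(round(sweep_length * noise$frame_rate)) - 1) /
    noise$frame_rate
  x <- rowSums(vapply(times, function(s)
    spike_kernel_waveform(t_grid - s, noise$kernel_amplitude,
                          noise$kernel_rise, noise$kernel_decay),
    numeric(length(t_grid))))
  fl_trace(x, noise$frame_rate)
}

# Ground-truth label lookup for generate_population() output.
truth_label <- function(pop, id, cond) {
  lab <- pop$truth$labels
  lab$label[lab$neuron_id == id & lab$condition == cond]
}

# Pooled detection statistics over a generated population, matching
# detected peak times (corrected for the known kernel peak delay) against
# the ground-truth trains within one frame.
detection_stats <- function(pop, conditions = names(pop$spikes),
                            params = detection_params()) {
  delay <- kernel_peak_delay(pop$noise$kernel_rise, pop$noise$kernel_decay)
  tol <- 1 / pop$noise$frame_rate
  matched <- n_ref <- n_det <- 0
  for (cond in conditions) {
    for (tr in seq_along(pop$traces[[cond]])) {
      for (id in names(pop$traces[[cond]][[tr]])) {
        det <- process_trace(pop$traces[[cond]][[tr]][[id]], params)
        det$times <- det$times - delay
        ref <- pop$spikes[[cond]][[tr]][[id]]
        m <- match_spike_trains(det, ref, tol)
        matched <- matched + m$n_matched
        n_ref <- n_ref + length(ref$times)
        n_det <- n_det + length(det$times)
      }
    }
  }
  list(recall = matched / n_ref, precision = matched / n_det)
}

# Response-map label accuracy against generator ground truth.
label_accuracy <- function(map, pop) {
  truth <- pop$truth$labels
  key <- paste(map$neuron_id, map$condition)
  mean(map$label == truth$label[match(key, paste(truth$neuron_id,
                                                 truth$condition))])
}
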