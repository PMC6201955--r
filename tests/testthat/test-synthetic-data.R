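test_that("population spec validates its probability vector and rate ranges", {
  expect_error(population_spec(p_multimodal = 0.5, p_unimodal = 0.5,
                               p_nonparticipant = 0.5),
               "sum to 1")
  expect_error(population_spec(baseline_rate_range = c(-1, 5)),
               "positive")
  expect_error(population_spec(evoked_rate_range = c(0.1, 3)),
               "evoked maximum")
  expect_error(trace_noise_spec(sweep_length = 0), "sweep_length")
})

test_that("degenerate all-nonparticipant mix yields only nonresponsive labels", {
  spec <- population_spec(n_neurons = 12, p_multimodal = 0,
                          p_unimodal = 0, p_nonparticipant = 1, seed = 5)
  pop <- generate_population(spec, n_trials = 1, render_traces = FALSE)
  expect_true(all(pop$truth$labels$label == "nonresponsive"))
  expect_true(all(pop$truth$neurons$modality == "nonparticipant"))
  # baseline-only rates: evoked equals baseline for nonresponsive neurons
  merged <- merge(pop$truth$labels, pop$truth$neurons, by = "neuron_id")
  expect_equal(merged$evoked_rate, merged$baseline_rate)
})

test_that("modality mix of the default generator sits in its binomial interval", {
  spec <- population_spec(n_neurons = 100, seed = 1)
  pop <- generate_population(spec, n_trials = 1, render_traces = FALSE)
  n_multi <- sum(pop$truth$neurons$modality == "multimodal")
  ci <- qbinom(c(0.025, 0.975), 100, 0.80)
  expect_gte(n_multi, ci[1])
  expect_lte(n_multi, ci[2])
})

test_that("noiseless rendering is an exact kernel superposition", {
  # all non-spike signal sources off: white noise, drift, and the shared
  # subthreshold co-fluctuation
  noise <- trace_noise_spec(gaussian_noise_sd = 0, drift_amplitude = 0,
                            sweep_length = 20)
  spec <- population_spec(n_neurons = 3, shared_mod_amplitude = 0, seed = 11)
  pop <- generate_population(spec, noise, n_trials = 1)
  t_grid <- trace_times(pop$traces$IV[[1]][[1]])
  for (id in names(pop$traces$IV[[1]])) {
    trace <- pop$traces$IV[[1]][[id]]
    st <- pop$spikes$IV[[1]][[id]]$times
    manual <- Reduce(`+`, lapply(st, function(s)
      spike_kernel_waveform(t_grid - s, noise$kernel_amplitude,
                            noise$kernel_rise, noise$kernel_decay)),
      accumulate = FALSE, init = numeric(length(t_grid)))
    expect_lt(max(abs(trace$samples - manual)), 1e-12)
  }
})

test_that("generation is bit-identical for a fixed seed", {
  spec <- population_spec(n_neurons = 6, seed = 77)
  a <- generate_population(spec, n_trials = 2)
  b <- generate_population(spec, n_trials = 2)
  expect_identical(a$truth, b$truth)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$traces, b$traces)
})

test_that("empirical rates stay inside the stated physiological bands", {
  spec <- population_spec(n_neurons = 80, seed = 9, shared_mod_amplitude = 0)
  pop <- generate_population(spec, n_trials = 2, render_traces = FALSE)
  prot <- pop$protocols$IV
  # baseline firing measured over the prestimulus window
  base_rates <- vapply(names(pop$spikes$IV[[1]]), function(id) {
    mean(vapply(pop$spikes$IV, function(sweep)
      firing_frequency(sweep[[id]], prot$stim_pre), numeric(1)))
  }, numeric(1))
  # allow Poisson sampling noise around the [0.33, 6.8] band
  expect_lt(max(base_rates), 6.8 + 3 * sqrt(6.8 / 12))
  # evoked rates are capped at 14 Hz by construction
  expect_lte(max(pop$truth$labels$evoked_rate), 14)
  expect_gt(min(pop$truth$neurons$baseline_rate), 0.33 - 1e-12)
})

test_that("unimodal ground-truth labels respond in exactly one condition", {
  spec <- population_spec(n_neurons = 60, seed = 21)
  pop <- generate_population(spec, n_trials = 1, render_traces = FALSE)
  lab <- pop$truth$labels
  wide <- table(lab$neuron_id[lab$label != "nonresponsive"])
  uni <- pop$truth$neurons$neuron_id[pop$truth$neurons$modality == "unimodal"]
  expect_true(all(wide[uni] == 1))
})

test_that("pyloric generator: null effects leave burst metrics unchanged", {
  trains <- generate_pyloric(list(cycle_period = 0), jitter_sd = 0.005,
                             seed = 4)
  prot <- stim_protocol("IV", 40, onset = 10, offset = 16)
  res <- analyze_condition(trains, prot, exclusion = 1.5)
  expect_true(all(abs(res$norm_delta) < 0.05, na.rm = TRUE))
})

test_that("pyloric generator: +50% period change is recovered by the analysis", {
  trains <- generate_pyloric(list(cycle_period = 0.5), jitter_sd = 0.005,
                             onset = 10, offset = 16, duration = 34, seed = 8)
  prot <- stim_protocol("IV", 40, onset = 10, offset = 16)
  res <- analyze_condition(trains, prot, exclusion = 1.5)
  per <- res$norm_delta[res$unit == "PD" & res$metric == "cycle_period"]
  expect_equal(per, 0.5, tolerance = 0.05)
})

test_that("pyloric bursts follow the PD -> LP -> PY order in every cycle", {
  trains <- generate_pyloric(list(), jitter_sd = 0, seed = 2)
  pd <- segment_bursts(trains$PD)
  lp <- segment_bursts(trains$LP)
  py <- segment_bursts(trains$PY)
  n <- min(nrow(pd), nrow(lp), nrow(py))
  expect_true(all(pd$onset[seq_len(n)] < lp$onset[seq_len(n)]))
  expect_true(all(lp$onset[seq_len(n)] < py$onset[seq_len(n)]))
  expect_true(all(py$onset[seq_len(n)] < pd$onset[seq_len(n)] +
                    attr(trains, "truth")$pre_period + 1e-9))
})

test_that("pyloric generator rejects changes producing impossible bursts", {
  expect_error(generate_pyloric(list(cycle_period = -1.5)), "period")
  expect_error(generate_pyloric(list(burst_duration = -1.2)), "duration")
  expect_error(generate_pyloric(list(cycle_period = -0.5)), "overlap")
})
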