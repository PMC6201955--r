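make_time_grid <- function(n = 5000, fr = 250) (seq_len(n) - 1) / fr

test_that("remove_drift cancels a pure degree-6 polynomial exactly", {
  t <- make_time_grid()
  u <- 2 * t / max(t) - 1
  y <- 3 - 2 * u + 0.5 * u^3 + 2 * u^6
  out <- remove_drift(fl_trace(y), degree = 6)
  expect_lt(max(abs(out$samples)) / max(abs(y)), 1e-8)
})

test_that("remove_drift recovers a sine riding on polynomial drift", {
  t <- make_time_grid()
  u <- 2 * t / max(t) - 1
  sine <- sin(2 * pi * 30 * t)
  y <- (1 + 4 * u^2 - u^5) + sine
  out <- remove_drift(fl_trace(y), degree = 6)
  # independent oracle: residual of a direct least-squares fit on the input
  fit <- lm.fit(cbind(1, poly(t, 6)), y)$fitted.values
  expect_equal(out$samples, y - as.numeric(fit), tolerance = 1e-12)
  # the only recovery error is the sine leakage into the polynomial basis,
  # ~1% of amplitude (largest at the sweep edges)
  leakage <- max(abs(lm.fit(cbind(1, poly(t, 6)), sine)$fitted.values))
  expect_lt(leakage, 0.015)
  expect_lte(max(abs(out$samples - sine)), leakage + 1e-12)
})

test_that("remove_drift is idempotent and guards short traces", {
  t <- make_time_grid(400)
  y <- cumsum(rnorm(400)) / 10
  once <- remove_drift(fl_trace(y), 6)
  twice <- remove_drift(once, 6)
  expect_lt(max(abs(twice$samples - once$samples)) /
              max(abs(once$samples)), 1e-10)
  expect_error(remove_drift(fl_trace(rnorm(5)), 6), "too short")
})

test_that("tune_highpass separates spikes from slow sway", {
  fr <- 250
  t <- make_time_grid(5000, fr)
  sway <- 0.5 * sin(2 * pi * 2 * t)
  spikes <- trace_with_kernels(seq(1, 19, by = 0.7))$samples
  trace <- fl_trace(sway + spikes, fr)
  params <- detection_params(highpass_cutoffs = c(5, 20, 50))
  cutoff <- tune_highpass(trace, params)
  filtered <- highpass_trace(trace, cutoff)
  sway_only <- highpass_trace(fl_trace(sway, fr), cutoff)
  # band-power oracle: direct power of the filtered sway vs its input
  expect_gt(sum(sway^2) / sum(sway_only$samples^2), 100)
  expect_gt(max(filtered$samples), 0.8 * max(spikes))
})

test_that("tune_highpass degenerate cases: single candidate, pure slow trace", {
  t <- make_time_grid(2000)
  slow <- fl_trace(sin(2 * pi * 1 * t))
  expect_equal(tune_highpass(slow, detection_params(highpass_cutoffs = 20)),
               20)
  # with no fast content every cutoff scores ~(leakage - amplitude); the
  # leakage shrinks with the cutoff, so the score rule picks the lowest
  expect_equal(tune_highpass(slow,
                             detection_params(highpass_cutoffs = c(5, 20, 50))),
               5)
})

test_that("detect_spikes finds embedded kernels and nothing in silence", {
  true_times <- c(1.2, 2.345, 4, 5.5, 7.77, 9.1, 12, 14.6, 17, 19.2)
  trace <- trace_with_kernels(true_times)
  st <- detect_spikes(trace)
  expect_length(st$times, 10)
  delay <- kernel_peak_delay()
  expect_true(all(abs(st$times - delay - true_times) <= 1 / 250 + 1e-9))
  empty <- detect_spikes(fl_trace(numeric(1000)))
  expect_length(empty$times, 0)
})

test_that("detect_spikes honours the refractory window", {
  # two kernels 2 ms apart fuse into a single detected event at 4 ms
  trace <- trace_with_kernels(c(5, 5.002))
  st <- detect_spikes(trace, detection_params(refractory = 0.004))
  expect_length(st$times, 1)
})

test_that("match_spike_trains mirrors the misdetection bookkeeping", {
  ref <- spike_train(seq(0.1, by = 0.17, length.out = 114), "ref",
                     "intracellular")
  # drop 4 reference spikes, add 2 spurious events
  test_times <- sort(c(ref$times[-c(10, 30, 60, 100)] + 0.001,
                       c(5.05, 9.021)))
  test <- spike_train(test_times, "opt", "optical")
  m <- match_spike_trains(test, ref, tolerance = 0.005)
  expect_equal(m$under, 4)
  expect_equal(m$over, 2)
  expect_equal(m$misdetections, 6)
  # identity and empty-train edge cases
  ident <- match_spike_trains(ref, ref, 0.004)
  expect_equal(ident$misdetections, 0)
  expect_true(all(ident$latencies == 0))
  none <- match_spike_trains(spike_train(numeric(0)), ref, 0.004)
  expect_equal(none$under, 114)
  expect_equal(none$misdetections, 114)
})

test_that("match_spike_trains is symmetric under swapping the trains", {
  set.seed(31)
  for (rep in 1:5) {
    a <- spike_train(sort(runif(40, 0, 20)) + 0, "a")
    b <- spike_train(sort(runif(35, 0, 20)) + 0, "b")
    m1 <- match_spike_trains(a, b, 0.05)
    m2 <- match_spike_trains(b, a, 0.05)
    expect_equal(m1$over, m2$under)
    expect_equal(m1$under, m2$over)
    expect_equal(m1$misdetections, m2$misdetections)
  }
  expect_error(match_spike_trains(spike_train(1), spike_train(1), -1),
               "tolerance")
})

test_that("firing_frequency uses half-open windows", {
  st <- spike_train(c(0.5, 1.5, 2.5))
  expect_equal(firing_frequency(st, c(1, 3)), 1)   # 2 spikes / 2 s
  expect_equal(firing_frequency(spike_train(numeric(0)), c(0, 6)), 0)
  st12 <- spike_train(seq(0.25, by = 0.5, length.out = 12))
  expect_equal(firing_frequency(st12, c(0, 6)), 2)
  expect_error(firing_frequency(st, c(2, 2)), "window")
})

test_that("detection recall and precision exceed 0.95 at SNR 10", {
  spec <- population_spec(n_neurons = 12, seed = 123)
  pop <- generate_population(spec, trace_noise_spec(), n_trials = 1)
  stats <- detection_stats(pop)
  expect_gte(stats$recall, 0.95)
  expect_gte(stats$precision, 0.95)
})
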