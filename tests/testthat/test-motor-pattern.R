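test_that("burst segmentation follows the gap and minimum-spike rules", {
  st <- spike_train(c(0, 0.05, 0.1, 1.0, 1.05))
  b <- segment_bursts(st, gap_threshold = 0.2, min_spikes = 2)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_spikes, c(3, 2))
  expect_equal(b$duration, c(0.1, 0.05))
  # uniform 1-Hz firing never clusters at a 0.2-s gap
  slow <- spike_train(seq(0, 19, by = 1))
  expect_equal(nrow(segment_bursts(slow, 0.2, 2)), 0)
  expect_equal(nrow(segment_bursts(spike_train(numeric(0)))), 0)
  # every spike is assigned to at most one burst
  trains <- generate_pyloric(list(), seed = 3)
  for (u in names(trains)) {
    b <- segment_bursts(trains[[u]], min_spikes = 1)
    expect_equal(sum(b$n_spikes), length(trains[[u]]$times))
  }
})

test_that("cycle period is the mean of successive PD onset differences", {
  b <- data.frame(onset = c(0, 1, 2, 3), offset = c(0.2, 1.2, 2.2, 3.2),
                  n_spikes = 5, duration = 0.2)
  expect_equal(cycle_period(b), 1)
  b2 <- data.frame(onset = c(0, 1, 2.5), offset = c(0.2, 1.2, 2.7),
                   n_spikes = 5, duration = 0.2)
  expect_equal(cycle_period(b2), 1.25)
  expect_warning(p <- cycle_period(b[1, , drop = FALSE]), "undefined")
  expect_true(is.na(p))
})

test_that("normalized change is (post - pre)/pre with flagged degenerate pre", {
  expect_equal(normalized_change(2, 3)$norm_delta, 0.5)
  expect_equal(normalized_change(4, 4)$norm_delta, 0)
  expect_equal(normalized_change(2, 1)$norm_delta, -0.5)
  expect_warning(nd <- normalized_change(0, 1), "not positive")
  expect_true(is.na(nd$norm_delta))
})

test_that("burst onsets of generated trains match ground truth", {
  trains <- generate_pyloric(list(), jitter_sd = 0.005, seed = 10)
  truth <- attr(trains, "truth")
  pd <- segment_bursts(trains$PD)
  # onsets advance by about one period with small jitter
  expect_equal(mean(diff(pd$onset)), truth$pre_period, tolerance = 0.02)
  expect_equal(mean(pd$n_spikes), truth$params$PD$pre$n)
})

test_that("injected relative changes are recovered within 10%", {
  prot <- stim_protocol("IV", 40, onset = 12, offset = 18,
                        pre_duration = 10)
  run <- function(effects) {
    trains <- generate_pyloric(effects, onset = 12, offset = 18,
                               duration = 34, jitter_sd = 0.01, seed = 77)
    analyze_condition(trains, prot, exclusion = 1.5)
  }
  # cycle period +20%
  res <- run(list(cycle_period = 0.2))
  per <- res$norm_delta[res$unit == "PD" & res$metric == "cycle_period"]
  expect_lt(abs(per - 0.2) / 0.2, 0.1)
  # spikes per burst +25% on PD (8 -> 10 spikes), +20% on PY (10 -> 12)
  res <- run(list(spikes_per_burst = c(PD = 0.25, LP = 0, PY = 0.2)))
  spb_pd <- res$norm_delta[res$unit == "PD" & res$metric == "spikes_per_burst"]
  spb_py <- res$norm_delta[res$unit == "PY" & res$metric == "spikes_per_burst"]
  expect_lt(abs(spb_pd - 0.25) / 0.25, 0.1)
  expect_lt(abs(spb_py - 0.2) / 0.2, 0.1)
  # with an unchanged period, the window firing frequency tracks it
  ff_pd <- res$norm_delta[res$unit == "PD" & res$metric == "firing_frequency"]
  expect_lt(abs(ff_pd - 0.25) / 0.25, 0.1)
  # burst duration -20% on LP
  res <- run(list(burst_duration = c(PD = 0, LP = -0.2, PY = 0)))
  bd_lp <- res$norm_delta[res$unit == "LP" & res$metric == "burst_duration"]
  expect_lt(abs(bd_lp - (-0.2)) / 0.2, 0.1)
})

test_that("metrics are invariant under uniform time translation", {
  trains <- generate_pyloric(list(cycle_period = 0.2), jitter_sd = 0.005,
                             seed = 5)
  shift <- 3.25
  shifted <- lapply(trains, function(tr)
    spike_train(tr$times + shift, tr$unit_id, tr$source))
  prot0 <- stim_protocol("IV", 40, onset = 10, offset = 16)
  prot1 <- stim_protocol("IV", 40, onset = 10 + shift, offset = 16 + shift)
  r0 <- analyze_condition(trains, prot0, 1.5)
  r1 <- analyze_condition(shifted, prot1, 1.5)
  expect_equal(r1$norm_delta, r0$norm_delta, tolerance = 1e-9)
})

test_that("analyze_condition validates its windows", {
  trains <- generate_pyloric(list(), seed = 1, duration = 20)
  prot <- stim_protocol("IV", 40, onset = 10, offset = 16)
  expect_error(analyze_condition(trains, prot, exclusion = 10),
               "no post-stimulus data")
})
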