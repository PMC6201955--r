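prot6 <- stim_protocol("IV", 40, onset = 7)

regular_train <- function(rate, window) {
  if (rate == 0) return(numeric(0))
  seq(window[1] + 1e-4, window[2] - 1e-4, length.out = round(rate * diff(window)))
}

test_that("classify_response follows the count-difference sign rule", {
  pre <- regular_train(2, prot6$stim_pre)
  expect_equal(classify_response(
    spike_train(sort(c(pre, regular_train(40 / 6, prot6$stim_on)))), prot6,
    deadband = 1), "excited")
  same <- spike_train(sort(c(regular_train(2, prot6$stim_pre),
                             regular_train(2, prot6$stim_on))))
  expect_equal(classify_response(same, prot6, deadband = 1), "nonresponsive")
  inh <- spike_train(sort(c(regular_train(5, prot6$stim_pre),
                            regular_train(1, prot6$stim_on))))
  expect_equal(classify_response(inh, prot6, deadband = 1), "inhibited")
})

test_that("classify_response is antisymmetric under swapping PRE and ON", {
  swapped <- stim_protocol("IV", 40, onset = 7)
  swapped$stim_pre <- prot6$stim_on
  swapped$stim_on <- prot6$stim_pre
  set.seed(17)
  for (rep in 1:10) {
    st <- spike_train(sort(runif(60, 0, 14)))
    a <- classify_response(st, prot6, deadband = 1)
    b <- classify_response(st, swapped, deadband = 1)
    flip <- c(excited = "inhibited", inhibited = "excited",
              nonresponsive = "nonresponsive")
    expect_equal(b, unname(flip[a]))
  }
})

test_that("frequency ratio and difference follow their definitions", {
  st <- spike_train(sort(c(regular_train(2, prot6$stim_pre),
                           regular_train(4, prot6$stim_on))))
  expect_equal(frequency_ratio(st, prot6), 2)
  expect_equal(frequency_difference(st, prot6), 2)
  same <- spike_train(sort(c(regular_train(2, prot6$stim_pre),
                             regular_train(2, prot6$stim_on))))
  expect_equal(frequency_ratio(same, prot6), 1)
  # silent before stimulation -> omitted, not infinite
  silent_pre <- spike_train(regular_train(3, prot6$stim_on))
  expect_true(is.na(frequency_ratio(silent_pre, prot6)))
  expect_equal(frequency_difference(silent_pre, prot6), 3)
})

test_that("ratio distributions are max-normalized per preparation then averaged", {
  one <- build_ratio_distribution(list(rep(1.0, 7)))
  expect_equal(max(one$mean), 1)
  expect_equal(sum(one$mean > 0), 1)  # single occupied bin
  # identical preparations average to themselves
  r <- c(0.4, 0.8, 0.85, 1.3, 2.2)
  two <- build_ratio_distribution(list(r, r))
  one_p <- build_ratio_distribution(list(r))
  expect_equal(two$mean, one_p$mean)
  expect_true(all(two$sd == 0))
  # every preparation's normalized histogram peaks at 1
  set.seed(5)
  many <- build_ratio_distribution(lapply(1:4, function(i) rexp(50)))
  expect_equal(unname(apply(many$counts, 1, max)), rep(1, 4))
  expect_error(build_ratio_distribution(list(NA_real_)), "defined ratio")
})

test_that("compare_distributions reproduces K-S edge cases", {
  x <- c(0.1, 0.4, 0.9)
  expect_equal(compare_distributions(x, x)$D, 0)
  expect_equal(compare_distributions(0, 1)$D, 1)
  # shifted uniforms are reliably separated at n = 1000
  set.seed(8)
  rejected <- vapply(1:20, function(i) {
    compare_distributions(runif(1000), runif(1000, 0.5, 1.5))$p < 0.001
  }, logical(1))
  expect_gte(mean(rejected), 0.99)
})

test_that("response_latency finds the peak and breaks ties early", {
  fr <- 250
  x <- numeric(500)
  onset <- 0.5
  lat_true <- 0.032  # 8 frames after onset, exactly on the grid
  x[round((onset + lat_true) * fr) + 1] <- 1
  tr <- fl_trace(x, fr)
  expect_equal(response_latency(tr, onset), lat_true)
  flat <- fl_trace(numeric(500), fr)
  expect_equal(response_latency(flat, onset), 0)  # tie -> window start
  expect_error(response_latency(tr, onset, search_window = 10), "beyond")
})

test_that("latency measurement recovers the generator's latency distribution", {
  sim <- generate_latency_sweeps(n_neurons = 40, seed = 13)
  noise <- trace_noise_spec(sweep_length = 2)
  delay <- kernel_peak_delay(noise$kernel_rise, noise$kernel_decay)
  measured <- vapply(sim$mean_traces, response_latency, numeric(1),
                     onset = 0.5)
  # the optical peak lags the spike by the kernel peak delay
  se <- 0.0114 / sqrt(40)
  expect_lt(abs(mean(measured) - delay - 0.0297), 2 * se + 1 / 250)
})

test_that("classify_modality applies the two-condition definition", {
  map <- data.frame(
    neuron_id = rep(c("a", "b", "c", "d"), each = 2),
    condition = rep(c("IV", "VCN"), 4),
    label = c("excited", "inhibited",        # a: multimodal
              "nonresponsive", "excited",    # b: unimodal
              "nonresponsive", "nonresponsive",  # c: nonparticipant
              "inhibited", "inhibited"))     # d: multimodal
  out <- classify_modality(map)
  expect_equal(out$neurons$modality[match(c("a", "b", "c", "d"),
                                          out$neurons$neuron_id)],
               c("multimodal", "unimodal", "nonparticipant", "multimodal"))
  expect_equal(sum(out$proportions), 100)
  expect_error(classify_modality(map[map$condition == "IV", ]), "missing")
})

test_that("unique_responses enumerates all 27 label triples correctly", {
  labs <- c("excited", "inhibited", "nonresponsive")
  grid <- expand.grid(IV = labs, VCN = labs, bimodal = labs,
                      stringsAsFactors = FALSE)
  map <- data.frame(
    neuron_id = rep(sprintf("n%02d", seq_len(27)), times = 3),
    condition = rep(c("IV", "VCN", "bimodal"), each = 27),
    label = c(grid$IV, grid$VCN, grid$bimodal))
  out <- unique_responses(map)
  # independent enumeration of the definition
  expected <- apply(grid, 1, function(l) {
    if (length(unique(l)) == 1L) return("all_equal")
    if (length(unique(l)) == 3L) return("three_distinct")
    odd <- names(l)[l != l[duplicated(l) | duplicated(l, fromLast = TRUE)][1]]
    odd
  })
  got <- out$neurons$unique_to[match(sprintf("n%02d", 1:27),
                                     out$neurons$neuron_id)]
  expect_equal(got, unname(expected))
  # the worked example: excited by IV, inhibited by VCN and bimodal
  ex <- data.frame(neuron_id = "x", condition = c("IV", "VCN", "bimodal"),
                   label = c("excited", "inhibited", "inhibited"))
  expect_equal(unique_responses(ex)$neurons$unique_to, "IV")
})

test_that("full-pipeline label recovery exceeds 95% at high SNR", {
  spec <- population_spec(n_neurons = 60, seed = 19)
  pop <- generate_population(spec, n_trials = 6, render_traces = FALSE)
  map <- build_response_map(pop$spikes, pop$protocols)
  expect_gte(label_accuracy(map, pop), 0.95)
  # per-condition label proportions close over the population
  for (cond in c("IV", "VCN")) {
    sub <- map[map$condition == cond, ]
    expect_equal(sum(table(sub$label)) / nrow(sub), 1)
  }
})
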