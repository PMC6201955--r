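#' Classify a neuron's response to one stimulation
#'
#' Compares the spike count during stimulation (`stim_on`) with the count
#' in the equal-duration prestimulus window (`stim_pre`):
#' `delta = count(stim_on) - count(stim_pre)`; the neuron is `excited` if
#' `delta > deadband`, `inhibited` if `delta < -deadband`, else
#' `nonresponsive`. With several sweeps the counts are averaged across
#' sweeps before differencing, so `deadband` is in (possibly fractional)
#' spikes per window.
#'
#' The default dead-band is adaptive: `max(1, 2.33 * s)`, where `s =
#' sqrt((mean PRE count + mean ON count) / n_sweeps)` is the Poisson
#' standard error of the count difference. A fixed 1-spike dead-band
#' under-absorbs Poisson jitter at the upper end of the spontaneous-rate
#' range (a 6.8-Hz baseline has a count SD of ~6 per 6-s window), while
#' the adaptive band holds the false-call rate near 2% across the whole
#' range without suppressing real responses.
#'
#' @param train A [spike_train()], or a list of them (one per sweep).
#' @param protocol A [stim_protocol()]; `stim_pre` and `stim_on` must have
#'   equal duration.
#' @param deadband Dead-band in spikes. `NULL` (default) uses the adaptive
#'   rule above; a number fixes it.
#' @return `"excited"`, `"inhibited"` or `"nonresponsive"`.
#' @export
classify_response <- function(train, protocol, deadband = NULL) {
  check_protocol(protocol)
  if (!is.null(deadband)) check_number(deadband, "deadband", lower = 0)
  pre <- protocol$stim_pre; on <- protocol$stim_on
  if (abs(diff(pre) - diff(on)) > 1e-9)
    abort_bad_arg("protocol", "stim_pre and stim_on must have equal duration")
  trains <- if (inherits(train, "spike_train")) list(train) else train
  if (!length(trains)) abort_bad_arg("train", "must be non-empty")
  counts <- vapply(trains, function(tr) {
    check_spike_train(tr)
    c(spike_count(tr, pre), spike_count(tr, on))
  }, numeric(2))
  m_pre <- mean(counts[1, ]); m_on <- mean(counts[2, ])
  delta <- m_on - m_pre
  if (is.null(deadband))
    deadband <- max(1, 2.33 * sqrt((m_pre + m_on) / ncol(counts)))
  if (delta > deadband) "excited"
  else if (delta < -deadband) "inhibited"
  else "nonresponsive"
}

#' Stimulation/prestimulation frequency ratio
#'
#' Ratio of firing frequency during the 6-s stimulation window to the
#' frequency in the 6 s immediately preceding it. Neurons that were not
#' spontaneously active (prestimulus frequency 0) are omitted — the ratio
#' is `NA` — to avoid division by zero. Ratios > 1 indicate excitation,
#' < 1 inhibition. With several sweeps, frequencies are averaged across
#' sweeps first.
#'
#' @inheritParams classify_response
#' @return The frequency ratio, or `NA_real_` when the prestimulus
#'   frequency is zero.
#' @export
frequency_ratio <- function(train, protocol) {
  check_protocol(protocol)
  trains <- if (inherits(train, "spike_train")) list(train) else train
  f_pre <- mean(vapply(trains, firing_frequency, numeric(1),
                       window = protocol$stim_pre))
  f_on <- mean(vapply(trains, firing_frequency, numeric(1),
                      window = protocol$stim_on))
  if (f_pre == 0) return(NA_real_)
  f_on / f_pre
}

#' Stimulation minus prestimulation frequency difference
#'
#' The companion measure to [frequency_ratio()] that keeps neurons without
#' spontaneous activity in the analysis.
#'
#' @inheritParams classify_response
#' @return Frequency difference, Hz.
#' @export
frequency_difference <- function(train, protocol) {
  check_protocol(protocol)
  trains <- if (inherits(train, "spike_train")) list(train) else train
  mean(vapply(trains, firing_frequency, numeric(1),
              window = protocol$stim_on)) -
    mean(vapply(trains, firing_frequency, numeric(1),
                window = protocol$stim_pre))
}

#' Build a normalized frequency-ratio distribution
#'
#' Per preparation, the defined ratios are binned (bin width 0.1 from 0 to
#' the shared maximum, rounded up to the next bin edge) and the counts are
#' normalized to the maximum count of that preparation; the normalized
#' histograms are then averaged element-wise across preparations
#' (mean and SD).
#'
#' @param ratios_by_prep List with one numeric vector of ratios per
#'   preparation; `NA` entries (omitted neurons) are dropped.
#' @param bin_width Histogram bin width.
#' @return A list of class `ratio_distribution` with `bin_edges`,
#'   `mid`, per-preparation normalized `counts` (matrix, preparations in
#'   rows), and across-preparation `mean` and `sd`.
#' @export
build_ratio_distribution <- function(ratios_by_prep, bin_width = 0.1) {
  check_number(bin_width, "bin_width", lower = 1e-12)
  if (!is.list(ratios_by_prep)) ratios_by_prep <- list(ratios_by_prep)
  ratios_by_prep <- lapply(ratios_by_prep, function(r) r[!is.na(r)])
  if (!length(ratios_by_prep) || !any(lengths(ratios_by_prep) > 0))
    abort_bad_arg("ratios_by_prep",
                  "needs at least one preparation with a defined ratio")
  top <- max(unlist(ratios_by_prep))
  edges <- seq(0, ceiling(top / bin_width + 1e-9) * bin_width, by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  counts <- t(vapply(ratios_by_prep, function(r) {
    h <- graphics::hist(r, breaks = edges, plot = FALSE, right = FALSE)$counts
    if (max(h) > 0) h / max(h) else h
  }, numeric(length(edges) - 1L)))
  structure(list(bin_edges = edges,
                 mid = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 mean = colMeans(counts),
                 sd = apply(counts, 2, stats::sd)),
            class = "ratio_distribution")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper over [stats::ks.test()] returning the D statistic and the
#' p-value, the test used throughout to compare pooled response
#' distributions between sensory conditions.
#'
#' @param a,b Numeric samples (non-empty; `NA` dropped).
#' @return List with elements `D` and `p`.
#' @export
compare_distributions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    abort_bad_arg("a", "both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Peak response latency from a trial-averaged trace
#'
#' Time from stimulus onset to the peak of the trial-averaged optical
#' trace, searched within `[onset, onset + search_window]`. Ties resolve
#' to the earliest sample.
#'
#' @param mean_trace A trial-averaged [fl_trace()] (see
#'   [average_traces()]).
#' @param onset Stimulus onset, seconds.
#' @param search_window Search duration after onset, seconds (default
#'   100 ms, suited to single 1-Hz pulses).
#' @return Latency, seconds.
#' @export
response_latency <- function(mean_trace, onset, search_window = 0.1) {
  check_trace(mean_trace, "mean_trace")
  check_number(onset, "onset", lower = 0)
  check_number(search_window, "search_window", lower = 1e-9)
  t <- trace_times(mean_trace)
  if (onset < t[1] || onset + search_window > t[length(t)])
    abort_bad_arg("search_window", "window extends beyond the sweep")
  idx <- which(t >= onset & t <= onset + search_window)
  t[idx[which.max(mean_trace$samples[idx])]] - onset
}

#' Assemble a response map for a population
#'
#' Runs [classify_response()], [frequency_ratio()] and
#' [frequency_difference()] for every neuron and condition and returns the
#' tidy per-neuron, per-condition table that downstream modality,
#' congruency and spatial analyses consume.
#'
#' @param spikes Nested list `spikes[[condition]][[trial]][[neuron]]` of
#'   [spike_train()] objects (the shape produced by
#'   [generate_population()]).
#' @param protocols Named list of [stim_protocol()] per condition.
#' @param deadband Dead-band passed to [classify_response()] (default: its
#'   adaptive rule).
#' @param xy Optional data frame (`neuron_id`, `x`, `y`) of soma
#'   coordinates to join in.
#' @return A data frame of class `response_map`: `neuron_id`, `condition`,
#'   `label`, `freq_ratio`, `freq_diff` (plus `x`, `y` when given).
#' @export
build_response_map <- function(spikes, protocols, deadband = NULL, xy = NULL) {
  conds <- names(spikes)
  if (is.null(conds) || !all(conds %in% names(protocols)))
    abort_bad_arg("protocols", "must name a protocol for every condition")
  rows <- list()
  for (cond in conds) {
    trials <- spikes[[cond]]
    ids <- names(trials[[1]])
    for (id in ids) {
      per_neuron <- lapply(trials, `[[`, id)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = id, condition = cond,
        label = classify_response(per_neuron, protocols[[cond]], deadband),
        freq_ratio = frequency_ratio(per_neuron, protocols[[cond]]),
        freq_diff = frequency_difference(per_neuron, protocols[[cond]]),
        stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  if (!is.null(xy)) map <- merge(map, xy, by = "neuron_id", sort = FALSE)
  class(map) <- c("response_map", class(map))
  map
}

#' Classify neurons as multimodal, unimodal or nonparticipant
#'
#' A neuron is multimodal when both its IV and VCN labels are
#' non-nonresponsive, unimodal when exactly one is, and nonparticipant
#' when neither is. Population proportions are reported as a percentage of
#' neurons per ganglion.
#'
#' @param map A response map (data frame with `neuron_id`, `condition`,
#'   `label`) containing both `IV` and `VCN` rows for every neuron.
#' @return A list with `neurons` (data frame `neuron_id`, `modality`) and
#'   `proportions` (named percentages summing to 100).
#' @export
classify_modality <- function(map) {
  wide <- label_matrix(map, c("IV", "VCN"))
  responsive <- wide != "nonresponsive"
  n_resp <- rowSums(responsive)
  modality <- c("nonparticipant", "unimodal", "multimodal")[n_resp + 1L]
  neurons <- data.frame(neuron_id = rownames(wide), modality = modality,
                        stringsAsFactors = FALSE)
  props <- 100 * vapply(c("multimodal", "unimodal", "nonparticipant"),
                        function(m) mean(modality == m), numeric(1))
  list(neurons = neurons, proportions = props)
}

# neuron x condition label matrix, validating completeness
label_matrix <- function(map, conditions) {
  missing <- setdiff(conditions, unique(map$condition))
  if (length(missing))
    abort_bad_arg("map", paste("missing condition:",
                               paste(missing, collapse = ", ")))
  map <- map[map$condition %in% conditions, ]
  wide <- stats::reshape(
    map[, c("neuron_id", "condition", "label")],
    idvar = "neuron_id", timevar = "condition", direction = "wide")
  rn <- wide$neuron_id
  wide <- as.matrix(wide[, paste0("label.", conditions), drop = FALSE])
  colnames(wide) <- conditions
  rownames(wide) <- rn
  if (anyNA(wide))
    abort_bad_arg("map", "every neuron needs a label in every condition")
  wide
}

#' Identify condition-unique responses
#'
#' A neuron is unique to condition `c` when its labels in the other two
#' conditions are equal to each other but differ from its label in `c`.
#' Neurons with identical labels in all three conditions are omitted (not
#' unique participants); neurons with three pairwise-distinct labels do not
#' fit the definition either and are omitted and flagged.
#'
#' @param map A response map with `IV`, `VCN` and `bimodal` labels for
#'   every neuron.
#' @return List with `neurons` (data frame `neuron_id`, `unique_to`:
#'   condition name, `"all_equal"` or `"three_distinct"`) and `proportions`
#'   (percentage of all neurons unique to each condition).
#' @export
unique_responses <- function(map) {
  conds <- c("IV", "VCN", "bimodal")
  wide <- label_matrix(map, conds)
  unique_to <- apply(wide, 1, function(l) {
    nu <- length(unique(l))
    if (nu == 1L) return("all_equal")
    if (nu == 3L) return("three_distinct")
    conds[l != l[duplicated(l) | duplicated(l, fromLast = TRUE)][1]]
  })
  props <- 100 * vapply(conds, function(cc) mean(unique_to == cc), numeric(1))
  list(neurons = data.frame(neuron_id = rownames(wide),
                            unique_to = unname(unique_to),
                            stringsAsFactors = FALSE),
       proportions = props)
}
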