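#' Segment a motor-unit spike train into bursts
#'
#' Consecutive spikes with inter-spike intervals at or below the gap
#' threshold belong to one burst; bursts with fewer than `min_spikes`
#' spikes are discarded. The default gap of 0.2 s is ~20% of the pyloric
#' cycle period.
#'
#' @param train A [spike_train()].
#' @param gap_threshold Maximum within-burst inter-spike interval, s.
#' @param min_spikes Minimum spikes per burst.
#' @return A data frame of class `burst_series` with one row per burst:
#'   `onset`, `offset`, `n_spikes`, `duration` (first-to-last spike); the
#'   unit id is attached as attribute `"unit_id"`. An empty train yields
#'   zero rows.
#' @export
segment_bursts <- function(train, gap_threshold = 0.2, min_spikes = 2) {
  check_spike_train(train)
  check_number(gap_threshold, "gap_threshold", lower = 1e-12)
  check_number(min_spikes, "min_spikes", lower = 1)
  tt <- train$times
  if (!length(tt)) {
    out <- data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0), duration = numeric(0))
  } else {
    grp <- cumsum(c(1L, diff(tt) > gap_threshold))
    pieces <- split(tt, grp)
    out <- do.call(rbind, lapply(pieces, function(s) {
      data.frame(onset = s[1], offset = s[length(s)],
                 n_spikes = length(s), duration = s[length(s)] - s[1])
    }))
    out <- out[out$n_spikes >= min_spikes, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unit_id") <- train$unit_id
  class(out) <- c("burst_series", class(out))
  out
}

#' Pyloric cycle period from PD bursts
#'
#' Mean interval between the onsets of successive pacemaker (PD) bursts
#' within a window.
#'
#' @param pd A `burst_series` from the PD unit (see [segment_bursts()]).
#' @param window Optional `c(start, end)`; bursts whose onsets fall in
#'   `[start, end)` are used.
#' @return Mean period in seconds, or `NA_real_` (flagged by a warning)
#'   when fewer than two bursts are available.
#' @export
cycle_period <- function(pd, window = NULL) {
  on <- pd$onset
  if (!is.null(window)) {
    check_interval(window, "window")
    on <- on[on >= window[1] & on < window[2]]
  }
  if (length(on) < 2L) {
    warning("fewer than 2 PD bursts in window: cycle period undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(diff(on))
}

#' Normalized pre/post change
#'
#' `norm_delta = (post - pre) / pre`, the normalized change between the
#' prestimulus and poststimulus measurements of a motor metric. Undefined
#' (`NA`, flagged) when `pre` is not positive.
#'
#' @param pre,post Metric values before and after stimulation.
#' @param metric Optional metric name carried through.
#' @return A one-row data frame `metric`, `pre`, `post`, `norm_delta`.
#' @export
normalized_change <- function(pre, post, metric = NA_character_) {
  nd <- if (is.na(pre) || is.na(post) || pre <= 0) {
    if (!is.na(pre) && pre <= 0)
      warning("pre value not positive: normalized change undefined",
              call. = FALSE)
    NA_real_
  } else {
    (post - pre) / pre
  }
  data.frame(metric = metric, pre = pre, post = post, norm_delta = nd,
             stringsAsFactors = FALSE)
}

# metrics of one unit over one window
window_metrics <- function(train, bursts, window, is_pd) {
  sel <- bursts[bursts$onset >= window[1] & bursts$onset < window[2], ,
                drop = FALSE]
  list(
    firing_frequency = firing_frequency(train, window),
    spikes_per_burst = if (nrow(sel)) mean(sel$n_spikes) else NA_real_,
    burst_duration = if (nrow(sel)) mean(sel$duration) else NA_real_,
    cycle_period = if (is_pd) suppressWarnings(cycle_period(sel, window))
                   else NA_real_
  )
}

#' Pre/post motor-pattern analysis for one sensory condition
#'
#' Computes firing frequency, spikes per burst, burst duration and (from
#' PD) cycle period over the prestimulus window and over a poststimulus
#' window that starts only after an exclusion gap — dropping the first
#' pyloric cycle(s) after stimulation, where direct sensory effects on the
#' motor circuits have not yet subsided — and emits the normalized change
#' for every metric and unit.
#'
#' @param trains Named list of [spike_train()] objects (must include
#'   `PD`; typically also `LP` and `PY`).
#' @param protocol A [stim_protocol()]. Its `stim_pre` window is used as
#'   is; the post window is `[offset + exclusion, offset + exclusion +
#'   pre-duration)`.
#' @param exclusion Post-stimulus exclusion gap, seconds (the observed
#'   direct effects dissipate in roughly 1-2 s; default 1.5). Must not
#'   exceed the protocol's `post_gap`-based window, i.e. the post window
#'   must still fit the data.
#' @param gap_threshold,min_spikes Burst segmentation parameters.
#' @return Data frame with one row per unit and metric: `unit`, `metric`,
#'   `pre`, `post`, `norm_delta`.
#' @export
analyze_condition <- function(trains, protocol, exclusion = 1.5,
                              gap_threshold = 0.2, min_spikes = 2) {
  check_protocol(protocol)
  check_number(exclusion, "exclusion", lower = 0)
  if (!length(trains) || is.null(names(trains)))
    abort_bad_arg("trains", "must be a named list of spike trains")
  pre_dur <- diff(protocol$stim_pre)
  post <- c(protocol$offset + exclusion,
            protocol$offset + exclusion + pre_dur)
  max_t <- max(vapply(trains, function(tr) {
    check_spike_train(tr)
    if (length(tr$times)) max(tr$times) else 0
  }, numeric(1)))
  if (post[1] >= max_t)
    abort_bad_arg("exclusion", "exclusion leaves no post-stimulus data")
  rows <- list()
  for (u in names(trains)) {
    tr <- trains[[u]]
    bursts <- segment_bursts(tr, gap_threshold, min_spikes)
    mp <- window_metrics(tr, bursts, protocol$stim_pre, is_pd = u == "PD")
    mq <- window_metrics(tr, bursts, post, is_pd = u == "PD")
    for (metric in names(mp)) {
      if (metric == "cycle_period" && u != "PD") next
      row <- suppressWarnings(
        normalized_change(mp[[metric]], mq[[metric]], metric))
      row$unit <- u
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("unit", "metric", "pre", "post", "norm_delta")]
}
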