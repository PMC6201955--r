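#' Generate a synthetic triphasic pyloric rhythm
#'
#' Produces extracellular-style spike trains for the PD (pacemaker), LP and
#' PY motor units: bursts recur with the pyloric cycle period (~1 s), with
#' the three units bursting at fixed phase offsets so every cycle follows
#' the PD -> LP -> PY order. After the stimulus offset the requested
#' relative changes are applied, emulating a sensory condition's effect on
#' the motor pattern (e.g. the cycle-period increase after chemosensory IV
#' input and decrease after mechanosensory VCN input).
#'
#' Spikes within a burst are evenly spaced across the burst duration, so
#' the first-to-last-spike duration equals the programmed duration exactly;
#' spikes-per-burst counts are integers (deterministic rounding), so only
#' relative changes that map to whole spikes are exactly representable.
#'
#' @param condition_effects Named list of relative changes applied after
#'   `offset`: `cycle_period` (scalar), and optionally `spikes_per_burst`
#'   and `burst_duration`, each either a scalar or a named vector over
#'   units (`PD`, `LP`, `PY`). A value of 0.5 means +50%.
#' @param cycle_period Baseline pyloric period, seconds.
#' @param phase Named burst-onset phases (fraction of the cycle).
#' @param burst_duration Named baseline burst durations, seconds.
#' @param spikes_per_burst Named baseline spike counts per burst.
#' @param onset,offset Stimulus train window, seconds.
#' @param duration Total simulated time, seconds.
#' @param jitter_sd Gaussian jitter of burst onsets, as a fraction of the
#'   current cycle period.
#' @param seed Optional integer seed.
#' @return Named list of [spike_train()] objects (`PD`, `LP`, `PY`), with
#'   the per-regime ground truth attached as attribute `"truth"`.
#' @export
generate_pyloric <- function(condition_effects = list(cycle_period = 0),
                             cycle_period = 1,
                             phase = c(PD = 0, LP = 0.4, PY = 0.7),
                             burst_duration = c(PD = 0.25, LP = 0.2,
                                                PY = 0.25),
                             spikes_per_burst = c(PD = 8, LP = 6, PY = 10),
                             onset = 10, offset = 16, duration = 30,
                             jitter_sd = 0.01, seed = NULL) {
  check_number(cycle_period, "cycle_period", lower = 1e-9)
  check_number(onset, "onset", lower = 0)
  check_number(offset, "offset")
  check_number(duration, "duration", lower = 1e-9)
  check_number(jitter_sd, "jitter_sd", lower = 0)
  if (offset <= onset) abort_bad_arg("offset", "must exceed onset")
  units <- c("PD", "LP", "PY")
  eff <- function(metric, unit) {
    v <- condition_effects[[metric]]
    if (is.null(v)) return(0)
    if (length(v) == 1L && is.null(names(v))) return(as.numeric(v))
    as.numeric(v[[unit]] %||% 0)
  }
  per_eff <- eff("cycle_period", "PD")
  post_period <- cycle_period * (1 + per_eff)
  if (post_period <= 0)
    abort_bad_arg("condition_effects", "cycle_period change gives a non-positive period")
  regime <- function(t) if (t < offset) "pre" else "post"
  params <- list()
  for (u in units) {
    d_pre <- burst_duration[[u]]
    n_pre <- round(spikes_per_burst[[u]])
    d_post <- d_pre * (1 + eff("burst_duration", u))
    n_post <- round(n_pre * (1 + eff("spikes_per_burst", u)))
    if (d_post <= 0)
      abort_bad_arg("condition_effects", "burst_duration change gives a non-positive duration")
    if (n_post < 1)
      abort_bad_arg("condition_effects", "spikes_per_burst change gives an empty burst")
    params[[u]] <- list(pre = list(d = d_pre, n = n_pre),
                        post = list(d = d_post, n = n_post))
  }
  # triphasic non-overlap within a cycle, in both regimes
  for (reg in c("pre", "post")) {
    T <- if (reg == "pre") cycle_period else post_period
    st <- phase[units] * T
    en <- st + vapply(units, function(u) params[[u]][[reg]]$d, numeric(1))
    ord <- order(st)
    if (any(en[ord][-3] > st[ord][-1]) || max(en) > st[ord][1] + T)
      abort_bad_arg("condition_effects", "burst phases overlap within a cycle")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- stats::setNames(vector("list", 3L), units)
  t <- cycle_period * 0.2
  while (t < duration) {
    T <- if (regime(t) == "pre") cycle_period else post_period
    reg <- regime(t)
    for (u in units) {
      p <- params[[u]][[reg]]
      b0 <- t + phase[[u]] * T + stats::rnorm(1, 0, jitter_sd * T)
      if (b0 + p$d > duration) next
      sp <- if (p$n == 1L) b0 else b0 + p$d * (0:(p$n - 1L)) / (p$n - 1L)
      times[[u]] <- c(times[[u]], sp)
    }
    t <- t + T
  }
  out <- lapply(units, function(u) {
    tt <- sort(times[[u]])
    tt <- tt[c(TRUE, diff(tt) > 1e-9)]
    spike_train(tt, unit_id = u, source = "extracellular")
  })
  names(out) <- units
  attr(out, "truth") <- list(pre_period = cycle_period,
                             post_period = post_period, params = params,
                             onset = onset, offset = offset)
  out
}
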