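#' Population specification for the synthetic CoG generator
#'
#' Defines the statistical composition of a simulated commissural-ganglion
#' (CoG) population. Defaults are pinned to the values measured in this
#' preparation: 80% multimodal / 18% unimodal / 2% nonparticipant neurons,
#' spontaneous (baseline) firing between 0.33 and 6.8 Hz, evoked rates up
#' to 14 Hz, a 46.15% probability that a multimodal neuron flips response
#' sign between the chemosensory (IV) and mechanosensory (VCN) conditions,
#' and response latencies of 29.7 +/- 11.4 ms (IV) and 31.9 +/- 7.7 ms
#' (VCN).
#'
#' Per-condition excitation probabilities are conditional on a neuron
#' responding in that condition. The defaults (IV 0.51, VCN 0.55,
#' bimodal 0.64) are derived from the observed per-ganglion percentages of
#' excited vs inhibited neurons in each condition.
#'
#' For multimodal neurons the IV and VCN signs are drawn jointly so that
#' both per-condition excitation marginals and the sign-switch probability
#' are honoured simultaneously.
#'
#' @param n_neurons Number of somata in the imaged field.
#' @param p_multimodal,p_unimodal,p_nonparticipant Modality-class mixture;
#'   must sum to 1 within 1e-9.
#' @param p_excited Named probabilities (conditions `IV`, `VCN`, `bimodal`)
#'   that a responsive neuron is excited rather than inhibited.
#' @param p_unimodal_iv Probability that a unimodal neuron's single
#'   responsive condition is IV (vs VCN).
#' @param p_sign_switch Probability a multimodal neuron has opposite signs
#'   in the IV and VCN conditions.
#' @param p_bimodal_congruent Probability that, where the additive rule
#'   table yields an expectation, the observed bimodal label matches it
#'   (used when `bimodal_rule = "empirical"`). The default 0.512 reproduces
#'   the observed congruent/incongruent split among ruled neurons.
#' @param bimodal_composition Named probabilities of the three bimodal
#'   response labels observed across ganglia (excited / inhibited /
#'   nonresponsive); incongruent neurons draw their observed label from
#'   this composition restricted to labels differing from the expectation.
#' @param bimodal_rule `"empirical"` (congruent with probability
#'   `p_bimodal_congruent`) or `"additive"` (bimodal labels follow the
#'   additive expectation exactly wherever a rule exists).
#' @param baseline_rate_range Spontaneous firing-rate interval, Hz.
#' @param evoked_rate_range Evoked firing-rate interval, Hz; the upper end
#'   caps excited rates.
#' @param min_rate_step Minimum excess of an excited neuron's evoked rate
#'   over its baseline, Hz. The default 1.5 Hz is the smallest step for
#'   which a 6-s window count comparison over six sweeps can recover
#'   excitation reliably (the generator is required to admit >= 95%
#'   downstream label recovery); weaker steps are statistically
#'   indistinguishable from Poisson jitter at the upper baseline rates.
#' @param inhibition_factor Evoked rate of an inhibited neuron as a fraction
#'   of its baseline.
#' @param latency_mean,latency_sd Named per-condition response-latency mean
#'   and SD, seconds; draws are truncated at 0.
#' @param evoked_dispersion Trial-to-trial lognormal coefficient of
#'   variation of the evoked rate (0 = identical across trials; the source
#'   data do not constrain this, so it is exposed rather than guessed).
#' @param shared_mod_amplitude SD of a slow network co-fluctuation shared by
#'   all responsive neurons within a sweep, expressed as a fraction of each
#'   neuron's evoked rate deviation. Produces the within-condition
#'   correlations that functional-connectivity analysis feeds on.
#' @param spike_refractory Absolute refractory period, seconds: generated
#'   spikes closer than this are thinned, as real action potentials cannot
#'   occur back-to-back within a few milliseconds.
#' @param soma_region `"disc"` or `"square"`: convex region for uniform
#'   soma placement (no spatial clustering by default).
#' @param seed Integer seed making the generated population reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_neurons = 100,
                            p_multimodal = 0.80,
                            p_unimodal = 0.18,
                            p_nonparticipant = 0.02,
                            p_excited = c(IV = 0.51, VCN = 0.55,
                                          bimodal = 0.64),
                            p_unimodal_iv = 0.5,
                            p_sign_switch = 0.4615,
                            p_bimodal_congruent = 0.512,
                            bimodal_composition = c(excited = 0.5919,
                                                    inhibited = 0.3356,
                                                    nonresponsive = 0.0725),
                            bimodal_rule = c("empirical", "additive"),
                            baseline_rate_range = c(0.33, 6.8),
                            evoked_rate_range = c(1.33, 14),
                            min_rate_step = 1.5,
                            inhibition_factor = 0.2,
                            latency_mean = c(IV = 0.0297, VCN = 0.0319,
                                             bimodal = 0.0297),
                            latency_sd = c(IV = 0.0114, VCN = 0.0077,
                                           bimodal = 0.0114),
                            evoked_dispersion = 0,
                            shared_mod_amplitude = 0.3,
                            spike_refractory = 0.004,
                            soma_region = c("disc", "square"),
                            seed = NULL) {
  bimodal_rule <- match.arg(bimodal_rule)
  soma_region <- match.arg(soma_region)
  check_number(n_neurons, "n_neurons", lower = 1)
  check_prob(p_multimodal, "p_multimodal")
  check_prob(p_unimodal, "p_unimodal")
  check_prob(p_nonparticipant, "p_nonparticipant")
  if (abs(p_multimodal + p_unimodal + p_nonparticipant - 1) > 1e-9)
    abort_bad_arg("p_multimodal",
                  "modality-class probabilities must sum to 1 within 1e-9")
  for (cc in c("IV", "VCN", "bimodal"))
    check_prob(p_excited[[cc]], paste0("p_excited[", cc, "]"))
  check_prob(p_unimodal_iv, "p_unimodal_iv")
  check_prob(p_sign_switch, "p_sign_switch")
  check_prob(p_bimodal_congruent, "p_bimodal_congruent")
  for (ll in c("excited", "inhibited", "nonresponsive"))
    check_prob(bimodal_composition[[ll]],
               paste0("bimodal_composition[", ll, "]"))
  check_interval(baseline_rate_range, "baseline_rate_range")
  check_interval(evoked_rate_range, "evoked_rate_range")
  if (min(baseline_rate_range) <= 0)
    abort_bad_arg("baseline_rate_range", "rates must be positive")
  if (max(evoked_rate_range) < max(baseline_rate_range))
    abort_bad_arg("evoked_rate_range",
                  "evoked maximum must be >= baseline maximum")
  check_number(min_rate_step, "min_rate_step", lower = 0)
  check_prob(inhibition_factor, "inhibition_factor")
  check_number(evoked_dispersion, "evoked_dispersion", lower = 0)
  check_number(shared_mod_amplitude, "shared_mod_amplitude", lower = 0)
  check_number(spike_refractory, "spike_refractory", lower = 0)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(as.list(environment()), class = "population_spec")
}

#' Trace noise and rendering specification
#'
#' Controls how ground-truth spike trains are rendered into fluorescence
#' traces: sampling (250 frames/s, 20-s sweeps), a random degree-6
#' polynomial baseline drift scaled to a given peak-to-peak amplitude,
#' additive Gaussian noise, and a biexponential spike kernel roughly four
#' frames wide, mimicking undersampled optical action potentials.
#'
#' The kernel signal-to-noise ratio is `kernel_amplitude /
#' gaussian_noise_sd`; the defaults give SNR 10.
#'
#' @param frame_rate Frames per second.
#' @param sweep_length Sweep duration, seconds.
#' @param drift_poly_degree Degree of the random drift polynomial.
#' @param drift_amplitude Peak-to-peak drift amplitude, fluorescence units.
#' @param gaussian_noise_sd SD of additive white noise, fluorescence units.
#' @param kernel_amplitude Peak amplitude of one spike's optical transient.
#' @param kernel_rise,kernel_decay Biexponential time constants, seconds.
#' @param subthreshold_gain Amplitude of the slow shared subthreshold
#'   component rendered into the traces of responsive neurons during
#'   stimulation, in units of `kernel_amplitude` per unit of the shared
#'   network co-fluctuation. Voltage-sensitive-dye signals carry slow
#'   membrane-potential changes that are often larger than the
#'   undersampled spikes; this is what trace-level coherence analysis
#'   picks up, while spike detection removes it with the high-pass stage.
#' @return An object of class `trace_noise_spec`.
#' @export
trace_noise_spec <- function(frame_rate = 250, sweep_length = 20,
                             drift_poly_degree = 6, drift_amplitude = 0.2,
                             gaussian_noise_sd = 0.01,
                             kernel_amplitude = 0.1,
                             kernel_rise = 1.5e-3, kernel_decay = 5e-3,
                             subthreshold_gain = 1.5) {
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(sweep_length, "sweep_length", lower = 1e-9)
  check_number(drift_poly_degree, "drift_poly_degree", lower = 0)
  check_number(drift_amplitude, "drift_amplitude", lower = 0)
  check_number(gaussian_noise_sd, "gaussian_noise_sd", lower = 0)
  check_number(kernel_amplitude, "kernel_amplitude", lower = 0)
  check_number(kernel_rise, "kernel_rise", lower = 1e-12)
  check_number(kernel_decay, "kernel_decay", lower = 1e-12)
  if (kernel_decay <= kernel_rise)
    abort_bad_arg("kernel_decay", "must exceed kernel_rise")
  check_number(subthreshold_gain, "subthreshold_gain", lower = 0)
  structure(as.list(environment()), class = "trace_noise_spec")
}

#' Biexponential optical spike kernel
#'
#' Waveform of a single spike's fluorescence transient:
#' `exp(-t/decay) - exp(-t/rise)` for `t >= 0`, scaled so its peak equals
#' `amplitude`; zero for `t < 0`.
#'
#' @param t Times relative to the spike, seconds.
#' @param amplitude Peak amplitude.
#' @param rise,decay Time constants, seconds (`decay > rise`).
#' @return Numeric vector of kernel values at `t`.
#' @export
spike_kernel_waveform <- function(t, amplitude = 0.1, rise = 1.5e-3,
                                  decay = 5e-3) {
  tp <- kernel_peak_delay(rise, decay)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- amplitude * (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / peak
  out
}

#' Time from spike to kernel peak
#'
#' The biexponential kernel peaks `rise*decay/(decay-rise) *
#' log(decay/rise)` seconds after the spike; peak-latency measurements on
#' rendered traces carry this constant offset.
#'
#' @inheritParams spike_kernel_waveform
#' @return Peak delay in seconds.
#' @export
kernel_peak_delay <- function(rise = 1.5e-3, decay = 5e-3) {
  rise * decay / (decay - rise) * log(decay / rise)
}

# Render spike times into a sampled trace (kernel superposition only).
render_spike_samples <- function(times, t_grid, noise) {
  x <- numeric(length(t_grid))
  if (!length(times)) return(x)
  dt <- t_grid[2] - t_grid[1]
  support <- noise$kernel_rise + 30 * noise$kernel_decay  # tail < 1e-13
  n_sup <- ceiling(support / dt) + 1L
  for (s in times) {
    i0 <- max(1L, ceiling((s - t_grid[1]) / dt) + 1L)
    i1 <- min(length(t_grid), i0 + n_sup)
    if (i0 > length(t_grid)) next
    idx <- i0:i1
    x[idx] <- x[idx] +
      spike_kernel_waveform(t_grid[idx] - s, noise$kernel_amplitude,
                            noise$kernel_rise, noise$kernel_decay)
  }
  x
}

# Random degree-d polynomial over the sweep, scaled to peak-to-peak
# amplitude `amp`.
random_drift <- function(t_grid, degree, amp) {
  if (amp <= 0 || degree < 1) return(numeric(length(t_grid)))
  u <- 2 * (t_grid - t_grid[1]) / (t_grid[length(t_grid)] - t_grid[1]) - 1
  coef <- stats::rnorm(degree + 1)
  y <- outer(u, 0:degree, `^`) %*% coef
  rng <- diff(range(y))
  if (rng < 1e-12) return(numeric(length(t_grid)))
  as.numeric((y - min(y)) / rng * amp)
}

# Sample spike times from a piecewise-constant-rate Poisson process over
# [w[1], w[2]) at `rate` Hz, optionally thinned against a modulation
# lookup (rate multiplier per frame).
sample_poisson_segment <- function(rate, w, mod_fun = NULL) {
  if (rate <= 0) return(numeric(0))
  dur <- w[2] - w[1]
  if (is.null(mod_fun)) {
    n <- stats::rpois(1L, rate * dur)
    return(sort(stats::runif(n, w[1], w[2])))
  }
  # thinning against time-varying rate rate*(mod(t)), mod >= 0
  mx <- max(rate * mod_fun(seq(w[1], w[2], length.out = 64L)))
  if (mx <= 0) return(numeric(0))
  n <- stats::rpois(1L, mx * dur)
  tt <- sort(stats::runif(n, w[1], w[2]))
  keep <- stats::runif(n) < (rate * mod_fun(tt)) / mx
  tt[keep]
}

# Joint IV/VCN sign distribution for multimodal neurons honouring both
# excitation marginals and the sign-switch probability.
multimodal_sign_joint <- function(p_ex_iv, p_ex_vcn, p_switch) {
  a <- (p_ex_iv + p_ex_vcn - p_switch) / 2  # P(ex, ex)
  b <- p_ex_iv - a                          # P(ex, inh)
  c <- p_ex_vcn - a                         # P(inh, ex)
  d <- 1 - a - b - c                        # P(inh, inh)
  p <- c(a, b, c, d)
  if (any(p < -1e-9))
    abort_bad_arg("p_sign_switch",
                  "incompatible with the per-condition excitation probabilities")
  pmax(p, 0) / sum(pmax(p, 0))
}

draw_truncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < 0)
  }
  x
}

#' Generate a ground-truth-labelled synthetic CoG population
#'
#' Draws modality classes, per-condition response labels, firing rates,
#' latencies and soma coordinates per [population_spec()]; simulates spike
#' trains from an inhomogeneous Poisson process whose rate steps from
#' baseline to the condition-dependent evoked rate at stimulus onset plus
#' the neuron's latency (scaled down by the inhibition factor for inhibited
#' neurons); and, optionally, renders each train into a fluorescence trace
#' as kernel pulses added to polynomial drift and Gaussian noise.
#'
#' The output is deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @param noise A [trace_noise_spec()].
#' @param protocols List of [stim_protocol()] objects, one per sensory
#'   condition to simulate (each condition occupies its own sweeps). May
#'   include a `"bimodal"` protocol; labels then follow the additive
#'   expectation machinery (see `bimodal_rule` in [population_spec()]).
#' @param n_trials Sweeps per condition.
#' @param render_traces If `FALSE`, only spike trains and ground truth are
#'   produced (much faster; used when downstream analysis starts from spike
#'   times).
#' @return A list with elements
#'   \describe{
#'     \item{spikes}{`spikes[[condition]][[trial]][[neuron]]`, each a
#'       [spike_train()].}
#'     \item{traces}{same shape, each an [fl_trace()] (or `NULL`).}
#'     \item{truth}{ground truth: `neurons` (id, modality, x, y,
#'       baseline_rate) and `labels` (id, condition, label, evoked_rate,
#'       latency) data frames.}
#'     \item{protocols, spec, noise}{inputs echoed back.}
#'   }
#' @export
generate_population <- function(spec = population_spec(),
                                noise = trace_noise_spec(),
                                protocols = list(stim_protocol("IV", 40),
                                                 stim_protocol("VCN", 15)),
                                n_trials = 6, render_traces = TRUE) {
  if (!inherits(spec, "population_spec"))
    abort_bad_arg("spec", "must be a population_spec")
  if (!inherits(noise, "trace_noise_spec"))
    abort_bad_arg("noise", "must be a trace_noise_spec")
  if (!length(protocols)) abort_bad_arg("protocols", "must be non-empty")
  for (p in protocols) {
    check_protocol(p)
    if (p$offset > noise$sweep_length)
      abort_bad_arg("protocols", "stimulus train extends beyond the sweep")
  }
  conds <- vapply(protocols, function(p) p$condition, character(1))
  if (anyDuplicated(conds))
    abort_bad_arg("protocols", "one protocol per condition")
  names(protocols) <- conds
  if (!is.null(spec$seed)) set.seed(spec$seed)

  n <- spec$n_neurons
  ids <- sprintf("n%03d", seq_len(n))
  modality <- sample(c("multimodal", "unimodal", "nonparticipant"), n,
                     replace = TRUE,
                     prob = c(spec$p_multimodal, spec$p_unimodal,
                              spec$p_nonparticipant))

  # per-neuron unimodal labels for IV and VCN
  lab <- matrix("nonresponsive", n, 2,
                dimnames = list(ids, c("IV", "VCN")))
  joint <- multimodal_sign_joint(spec$p_excited[["IV"]],
                                 spec$p_excited[["VCN"]],
                                 spec$p_sign_switch)
  combos <- matrix(c("excited", "excited",
                     "excited", "inhibited",
                     "inhibited", "excited",
                     "inhibited", "inhibited"), ncol = 2, byrow = TRUE)
  for (i in seq_len(n)) {
    if (modality[i] == "multimodal") {
      k <- sample.int(4L, 1L, prob = joint)
      lab[i, ] <- combos[k, ]
    } else if (modality[i] == "unimodal") {
      cond <- if (stats::runif(1) < spec$p_unimodal_iv) "IV" else "VCN"
      lab[i, cond] <- if (stats::runif(1) < spec$p_excited[[cond]])
        "excited" else "inhibited"
    }
  }

  # bimodal labels where requested
  if ("bimodal" %in% conds) {
    bi <- character(n)
    for (i in seq_len(n)) {
      exp_lab <- expected_bimodal(lab[i, "IV"], lab[i, "VCN"])
      if (identical(exp_lab, "no_rule")) {
        bi[i] <- if (stats::runif(1) < spec$p_excited[["bimodal"]])
          "excited" else "inhibited"
      } else if (spec$bimodal_rule == "additive" ||
                 stats::runif(1) < spec$p_bimodal_congruent) {
        bi[i] <- exp_lab
      } else {
        # incongruent: draw from the observed bimodal composition,
        # restricted to labels differing from the expectation
        others <- setdiff(c("excited", "inhibited", "nonresponsive"),
                          exp_lab)
        w <- spec$bimodal_composition[others]
        bi[i] <- sample(others, 1L, prob = w / sum(w))
      }
    }
    lab <- cbind(lab, bimodal = bi)
  }

  baseline <- stats::runif(n, spec$baseline_rate_range[1],
                           spec$baseline_rate_range[2])
  xy <- if (spec$soma_region == "disc") {
    r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  } else {
    cbind(x = stats::runif(n, -1, 1), y = stats::runif(n, -1, 1))
  }

  labels <- do.call(rbind, lapply(colnames(lab), function(cond) {
    lat <- draw_truncnorm_pos(n, spec$latency_mean[[cond]] %||% 0.03,
                              spec$latency_sd[[cond]] %||% 0.01)
    evoked <- baseline
    for (i in seq_len(n)) {
      if (lab[i, cond] == "excited") {
        lo <- max(spec$evoked_rate_range[1], baseline[i] + spec$min_rate_step)
        evoked[i] <- stats::runif(1, lo, spec$evoked_rate_range[2])
      } else if (lab[i, cond] == "inhibited") {
        evoked[i] <- baseline[i] * spec$inhibition_factor
      }
    }
    data.frame(neuron_id = ids, condition = cond, label = unname(lab[, cond]),
               evoked_rate = evoked, latency = lat,
               stringsAsFactors = FALSE)
  }))

  t_grid <- (seq_len(round(noise$sweep_length * noise$frame_rate)) - 1) /
    noise$frame_rate
  spikes <- traces <- stats::setNames(vector("list", length(conds)), conds)

  for (cond in conds) {
    prot <- protocols[[cond]]
    lab_c <- labels[labels$condition == cond, ]
    spikes[[cond]] <- vector("list", n_trials)
    traces[[cond]] <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      # shared slow co-fluctuation of evoked activity within this sweep
      mod_fun <- NULL
      if (spec$shared_mod_amplitude > 0) {
        raw <- stats::rnorm(length(t_grid))
        sm <- stats::filter(raw, rep(1 / 51, 51), sides = 2)
        sm[is.na(sm)] <- 0
        sm <- as.numeric(sm)
        if (stats::sd(sm) > 0)
          sm <- sm / stats::sd(sm) * spec$shared_mod_amplitude
        mod_fun <- stats::approxfun(t_grid, sm, rule = 2)
      }
      sweep_spikes <- vector("list", n)
      for (i in seq_len(n)) {
        b <- baseline[i]
        e <- lab_c$evoked_rate[i]
        if (spec$evoked_dispersion > 0 && lab_c$label[i] != "nonresponsive") {
          # lognormal trial-to-trial scaling with unit mean and CV = dispersion
          sdlog <- sqrt(log(1 + spec$evoked_dispersion^2))
          e <- e * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
        }
        lat <- lab_c$latency[i]
        step_t <- min(prot$onset + lat, prot$offset)
        seg1 <- sample_poisson_segment(b, c(0, step_t))
        seg3 <- sample_poisson_segment(b, c(prot$offset, noise$sweep_length))
        if (lab_c$label[i] == "nonresponsive" || is.null(mod_fun)) {
          seg2 <- sample_poisson_segment(e, c(step_t, prot$offset))
        } else {
          dev <- e - b
          f <- function(tt) pmax(0, (b + dev * (1 + mod_fun(tt))) / max(e, 1e-9))
          seg2 <- sample_poisson_segment(max(e, 1e-9), c(step_t, prot$offset),
                                         mod_fun = f)
        }
        st <- sort(c(seg1, seg2, seg3))
        if (length(st) > 1L) {
          # absolute refractory period: thin spikes that follow too closely
          keep <- rep(TRUE, length(st))
          last <- st[1]
          for (k in seq_along(st)[-1]) {
            if (st[k] - last < spec$spike_refractory) keep[k] <- FALSE
            else last <- st[k]
          }
          st <- st[keep]
        }
        sweep_spikes[[i]] <- spike_train(st, unit_id = ids[i],
                                         source = "optical")
      }
      names(sweep_spikes) <- ids
      spikes[[cond]][[tr]] <- sweep_spikes
      if (render_traces) {
        # slow shared subthreshold depolarisation visible in the dye
        # signal of responsive neurons during the stimulus train
        sub_base <- NULL
        if (!is.null(mod_fun) && noise$subthreshold_gain > 0) {
          gate <- t_grid >= prot$onset & t_grid < prot$offset
          sub_base <- mod_fun(t_grid) * gate *
            noise$subthreshold_gain * noise$kernel_amplitude
        }
        sweep_traces <- vector("list", n)
        for (i in seq_len(n)) {
          x <- render_spike_samples(sweep_spikes[[i]]$times, t_grid, noise) +
            random_drift(t_grid, noise$drift_poly_degree,
                         noise$drift_amplitude)
          if (!is.null(sub_base) && lab_c$label[i] != "nonresponsive") {
            dev_norm <- (lab_c$evoked_rate[i] - baseline[i]) /
              spec$evoked_rate_range[2]
            x <- x + dev_norm * sub_base
          }
          if (noise$gaussian_noise_sd > 0)
            x <- x + stats::rnorm(length(x), 0, noise$gaussian_noise_sd)
          sweep_traces[[i]] <- fl_trace(x, noise$frame_rate, ids[i],
                                        sweep_id = sprintf("%s_t%d", cond, tr))
        }
        names(sweep_traces) <- ids
        traces[[cond]][[tr]] <- sweep_traces
      }
    }
  }

  truth <- list(
    neurons = data.frame(neuron_id = ids, modality = modality,
                         x = xy[, "x"], y = xy[, "y"],
                         baseline_rate = baseline, stringsAsFactors = FALSE),
    labels = labels
  )
  list(spikes = spikes, traces = if (render_traces) traces else NULL,
       truth = truth, protocols = protocols, spec = spec, noise = noise)
}

#' Average fluorescence traces sample-wise
#'
#' Trial-averaging used before peak-latency measurement.
#'
#' @param traces List of [fl_trace()] objects of equal length and rate.
#' @return A single [fl_trace()] holding the mean trace.
#' @export
average_traces <- function(traces) {
  if (!length(traces)) abort_bad_arg("traces", "must be non-empty")
  for (tr in traces) check_trace(tr)
  len <- vapply(traces, function(tr) length(tr$samples), integer(1))
  if (length(unique(len)) != 1L)
    abort_bad_arg("traces", "must have equal length")
  m <- rowMeans(do.call(cbind, lapply(traces, `[[`, "samples")))
  out <- traces[[1]]
  out$samples <- m
  out$sweep_id <- "mean"
  out
}

#' Simulate single-pulse latency sweeps
#'
#' Emulates the low-frequency (1 Hz) latency protocol: each sweep contains
#' baseline firing plus one evoked spike at `onset + latency`, with the
#' latency drawn per neuron from a truncated normal and jittered per trial.
#' Used to validate peak-latency measurement on trial-averaged traces.
#'
#' @param n_neurons Number of neurons.
#' @param noise A [trace_noise_spec()].
#' @param onset Pulse time, seconds.
#' @param latency_mean,latency_sd Latency distribution, seconds.
#' @param n_trials Trials per neuron (averaged downstream).
#' @param baseline_rate Spontaneous rate outside the response, Hz.
#' @param seed Optional integer seed.
#' @return List with `mean_traces` (one averaged [fl_trace()] per neuron)
#'   and `true_latency` (numeric, the per-neuron mean latency drawn).
#' @export
generate_latency_sweeps <- function(n_neurons = 60,
                                    noise = trace_noise_spec(sweep_length = 2),
                                    onset = 0.5,
                                    latency_mean = 0.0297,
                                    latency_sd = 0.0114,
                                    n_trials = 6,
                                    baseline_rate = 0.5,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_grid <- (seq_len(round(noise$sweep_length * noise$frame_rate)) - 1) /
    noise$frame_rate
  mean_traces <- vector("list", n_neurons)
  true_latency <- draw_truncnorm_pos(n_neurons, latency_mean, latency_sd)
  for (i in seq_len(n_neurons)) {
    trials <- lapply(seq_len(n_trials), function(tr) {
      lat <- true_latency[i]
      st <- sort(c(sample_poisson_segment(baseline_rate,
                                          c(0, noise$sweep_length)),
                   onset + lat))
      x <- render_spike_samples(st, t_grid, noise)
      if (noise$gaussian_noise_sd > 0)
        x <- x + stats::rnorm(length(x), 0, noise$gaussian_noise_sd)
      fl_trace(x, noise$frame_rate, sprintf("n%03d", i),
               sweep_id = sprintf("t%d", tr))
    })
    mean_traces[[i]] <- average_traces(trials)
  }
  list(mean_traces = mean_traces, true_latency = true_latency)
}
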