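#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults equal to the study's
#' values where one exists (0.45 coherence threshold, 0.1 ratio bin width,
#' 6-s analysis windows, 250 frames/s, 1.5-s post-stimulus exclusion).
#' Unknown keys are rejected by name.
#'
#' @param ... Overrides of the default fields (see the function body for
#'   the full set: `seed`, `out_dir`, `stages`, `n_neurons`, `n_trials`,
#'   `conditions`, `deadband`, `coherence_threshold`,
#'   `require_significance`, `exclusion`, `bin_width`, `detection`,
#'   `noise`, `pyloric_effects`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "results/pipeline",
    stages = c("simulate", "detect", "classify", "connect", "spatial",
               "congruency", "motor"),
    n_neurons = 30,
    n_trials = 3,
    conditions = c("IV", "VCN", "bimodal"),
    deadband = NULL,
    coherence_threshold = 0.45,
    require_significance = FALSE,
    exclusion = 1.5,
    bin_width = 0.1,
    detection = detection_params(),
    noise = trace_noise_spec(),
    pyloric_effects = list(
      IV = list(cycle_period = 0.2),
      VCN = list(cycle_period = -0.1),
      bimodal = list(cycle_period = 0.1))
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    abort_bad_arg("config", paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, overrides)
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage))
    abort_bad_arg("stages", paste("unknown stage(s):",
                                  paste(bad_stage, collapse = ", ")))
  structure(cfg, class = "run_config")
}

protocol_for <- function(condition) {
  switch(condition,
         IV = stim_protocol("IV", 40),
         VCN = stim_protocol("VCN", 15),
         bimodal = stim_protocol("bimodal", 40),
         none = stim_protocol("none", 0.001))
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages — simulate, detect, classify, connect,
#' spatial, congruency, motor — on synthetic data, writing every product
#' under `config$out_dir` plus a manifest (seed, parameters, MD5 of every
#' file) so that runs are bit-reproducible: the same configuration and
#' seed yield identical file hashes.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config"))
    abort_bad_arg("config", "must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character(0)
  note <- function(p) written <<- c(written, p)
  stages <- config$stages
  protocols <- stats::setNames(lapply(config$conditions, protocol_for),
                               config$conditions)
  pop <- NULL
  detected <- NULL

  if ("simulate" %in% stages) {
    spec <- population_spec(n_neurons = config$n_neurons, seed = config$seed)
    pop <- generate_population(spec, config$noise, protocols,
                               n_trials = config$n_trials,
                               render_traces = TRUE)
    for (cond in config$conditions) {
      note(write_traces(pop$traces[[cond]][[1]],
                        out(sprintf("traces_%s_trial1.csv", cond))))
      note(write_spikes(pop$spikes[[cond]][[1]],
                        out(sprintf("true_spikes_%s_trial1.csv", cond))))
    }
    jsonlite::write_json(pop$truth, out("ground_truth.json"),
                         digits = NA, dataframe = "columns")
    note(out("ground_truth.json"))
  }
  if (any(c("detect", "classify", "connect") %in% stages)) {
    if (is.null(pop))
      abort_bad_arg("stages", "detect/classify/connect need the simulate stage")
  }

  if ("detect" %in% stages) {
    detected <- lapply(config$conditions, function(cond) {
      lapply(pop$traces[[cond]], function(sweep)
        lapply(sweep, process_trace, params = config$detection))
    })
    names(detected) <- config$conditions
    for (cond in config$conditions)
      note(write_spikes(detected[[cond]][[1]],
                        out(sprintf("detected_spikes_%s_trial1.csv", cond))))
  }

  map <- NULL
  if ("classify" %in% stages) {
    src <- if (!is.null(detected)) detected else pop$spikes
    xy <- pop$truth$neurons[, c("neuron_id", "x", "y")]
    map <- build_response_map(src, protocols, config$deadband, xy = xy)
    utils::write.csv(map, out("response_map.csv"), row.names = FALSE)
    note(out("response_map.csv"))
    if (all(c("IV", "VCN") %in% config$conditions)) {
      mod <- classify_modality(map)
      jsonlite::write_json(as.list(mod$proportions),
                           out("modality_proportions.json"),
                           auto_unbox = TRUE, digits = NA)
      note(out("modality_proportions.json"))
    }
  }

  if ("connect" %in% stages) {
    metrics <- list()
    for (cond in config$conditions) {
      traces <- lapply(pop$traces[[cond]][[1]], remove_drift)
      C <- coherence_matrix(traces, window = protocols[[cond]]$stim_on)
      G <- threshold_adjacency(C, config$coherence_threshold,
                               config$require_significance)
      note(write_graph_files(G,
                             out(sprintf("graph_%s.graphml", cond)),
                             out(sprintf("edges_%s.csv", cond)))[1])
      note(out(sprintf("edges_%s.csv", cond)))
      metrics[[cond]] <- list(K = G$K, m = G$m,
                              density = connectivity_density(G),
                              global_efficiency = global_efficiency(G))
    }
    jsonlite::write_json(metrics, out("connectivity_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    note(out("connectivity_metrics.json"))
  }

  if ("spatial" %in% stages) {
    if (is.null(map)) abort_bad_arg("stages", "spatial needs classify")
    geo <- population_geometry(pop$truth$neurons)
    utils::write.csv(geo, out("geometry.csv"), row.names = FALSE)
    note(out("geometry.csv"))
    summ <- list()
    for (cond in config$conditions) {
      sub <- merge(geo, map[map$condition == cond,
                            c("neuron_id", "label")], by = "neuron_id")
      summ[[cond]] <- lapply(split(sub, sub$label), function(s)
        list(n = nrow(s), mean_d_ratio = mean(s$d_ratio),
             angular_variance = if (sum(!is.na(s$angle)) > 0)
               angular_variance(s$angle) else NA))
    }
    jsonlite::write_json(summ, out("spatial_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note(out("spatial_summary.json"))
  }

  if ("congruency" %in% stages) {
    if (is.null(map)) abort_bad_arg("stages", "congruency needs classify")
    if (!all(c("IV", "VCN", "bimodal") %in% config$conditions))
      abort_bad_arg("conditions", "congruency needs IV, VCN and bimodal")
    rep <- score_congruency(map)
    utils::write.csv(rep$neurons, out("congruency_verdicts.csv"),
                     row.names = FALSE)
    note(out("congruency_verdicts.csv"))
    jsonlite::write_json(as.list(rep$proportions),
                         out("congruency_proportions.json"),
                         auto_unbox = TRUE, digits = NA)
    note(out("congruency_proportions.json"))
  }

  if ("motor" %in% stages) {
    motor_rows <- list()
    prot <- stim_protocol("IV", 40, onset = 10, offset = 16)
    for (cond in config$conditions) {
      eff <- config$pyloric_effects[[cond]] %||% list(cycle_period = 0)
      trains <- generate_pyloric(eff, onset = 10, offset = 16,
                                 duration = 30,
                                 seed = config$seed + match(cond,
                                                            config$conditions))
      res <- analyze_condition(trains, prot, config$exclusion)
      res$condition <- cond
      motor_rows[[cond]] <- res
    }
    motor <- do.call(rbind, motor_rows)
    utils::write.csv(motor, out("motor_metrics.csv"), row.names = FALSE)
    note(out("motor_metrics.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cogmap")),
    seed = config$seed,
    stages = stages,
    parameters = list(
      n_neurons = config$n_neurons, n_trials = config$n_trials,
      conditions = config$conditions, deadband = config$deadband,
      coherence_threshold = config$coherence_threshold,
      require_significance = config$require_significance,
      exclusion = config$exclusion, bin_width = config$bin_width,
      detection = unclass(config$detection),
      noise = unclass(config$noise)),
    files = as.list(tools::md5sum(sort(unique(written))))
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
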