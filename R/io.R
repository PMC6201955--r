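# Readers and writers for the pipeline's on-disk formats. All CSV is
# comma-separated UTF-8 with a header row, '.' decimal, times in seconds.

#' Write fluorescence traces to CSV
#'
#' Column 1 is time in seconds; one column per neuron.
#'
#' @param traces List of [fl_trace()] objects of equal length/rate.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  for (tr in traces) check_trace(tr)
  t <- trace_times(traces[[1]])
  mat <- vapply(traces, `[[`, numeric(length(t)), "samples")
  colnames(mat) <- vapply(traces, `[[`, character(1), "neuron_id")
  df <- data.frame(time_s = t, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fluorescence traces from CSV
#'
#' @param path File written by [write_traces()].
#' @param sweep_id Sweep id to stamp on the traces.
#' @return Named list of [fl_trace()] objects.
#' @export
read_traces <- function(path, sweep_id = "s1") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L)
    stop("malformed trace file (need time_s + >=1 neuron column): ", path,
         call. = FALSE)
  t <- df$time_s
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop("malformed trace file (non-uniform time axis): ", path,
         call. = FALSE)
  fr <- 1 / dt[1]
  ids <- setdiff(names(df), "time_s")
  out <- lapply(ids, function(id)
    fl_trace(df[[id]], frame_rate = fr, neuron_id = id,
             sweep_id = sweep_id, t0 = t[1]))
  stats::setNames(out, ids)
}

#' Write spike trains to CSV (`unit_id`, `time_s`)
#'
#' @param trains List of [spike_train()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    check_spike_train(tr)
    if (!length(tr$times)) return(NULL)
    data.frame(unit_id = tr$unit_id, time_s = tr$times,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(unit_id = character(0), time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' Rejects files whose times are not strictly increasing within a unit.
#'
#' @param path File written by [write_spikes()].
#' @param source Spike source tag for the resulting trains.
#' @return Named list of [spike_train()] objects.
#' @export
read_spikes <- function(path, source = "optical") {
  df <- utils::read.csv(path)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("malformed spike file (need unit_id, time_s): ", path,
         call. = FALSE)
  out <- lapply(split(df$time_s, df$unit_id), function(tt) tt)
  trains <- vector("list", length(out))
  for (k in seq_along(out)) {
    tt <- out[[k]]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      stop(sprintf("spike times not strictly increasing for unit '%s' in %s",
                   names(out)[k], path), call. = FALSE)
    trains[[k]] <- spike_train(tt, unit_id = names(out)[k], source = source)
  }
  stats::setNames(trains, names(out))
}

#' Write a functional graph to GraphML and edge-list CSV
#'
#' @param G A `functional_graph`.
#' @param graphml_path Output GraphML file (skipped if `NULL`).
#' @param edgelist_path Output edge-list CSV (`from`, `to`; skipped if
#'   `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_graph_files <- function(G, graphml_path = NULL, edgelist_path = NULL) {
  if (!inherits(G, "functional_graph"))
    abort_bad_arg("G", "must be a functional_graph")
  g <- igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected")
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(g)
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2]),
                     edgelist_path, row.names = FALSE)
  }
  invisible(c(graphml_path, edgelist_path))
}

#' Read a functional graph back from GraphML
#'
#' @param path GraphML file written by [write_graph_files()].
#' @return A `functional_graph`.
#' @export
read_graph_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A[A > 1] <- 1
  nm <- igraph::vertex_attr(g, "name")
  if (!is.null(nm)) dimnames(A) <- list(nm, nm)
  functional_graph(A)
}
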