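#' Pearson coherence matrix of a trace ensemble
#'
#' Computes the K x K matrix of Pearson correlation coefficients between
#' the fluorescence traces of all neuron pairs, over a restricted time
#' window (the 6-s stimulation window by default in the pipeline, since
#' the functional maps describe activity during stimulation). Constant
#' traces have undefined correlations; these entries are set to 0 and the
#' affected neurons flagged.
#'
#' @param traces List of [fl_trace()] objects (equal length, same frame
#'   rate), one per neuron.
#' @param window Optional `c(start, end)` window in seconds; `NULL` uses
#'   the whole sweep.
#' @return A list of class `coherence_matrix`: `rho` (symmetric, unit
#'   diagonal), `n` (samples used), `neuron_ids`, `constant` (logical
#'   flags).
#' @export
coherence_matrix <- function(traces, window = NULL) {
  if (length(traces) < 2L) abort_bad_arg("traces", "need at least 2 traces")
  for (tr in traces) check_trace(tr)
  ids <- vapply(traces, `[[`, character(1), "neuron_id")
  t <- trace_times(traces[[1]])
  keep <- if (is.null(window)) rep(TRUE, length(t)) else {
    check_interval(window, "window")
    t >= window[1] & t < window[2]
  }
  if (sum(keep) < 3L) abort_bad_arg("window", "selects fewer than 3 samples")
  V <- vapply(traces, function(tr) {
    if (length(tr$samples) != length(t))
      abort_bad_arg("traces", "must have equal length")
    tr$samples[keep]
  }, numeric(sum(keep)))
  constant <- apply(V, 2, function(v) stats::sd(v) < 1e-14)
  rho <- suppressWarnings(stats::cor(V))
  if (any(constant)) {
    warning("constant trace(s): correlations undefined, reported as 0",
            call. = FALSE)
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  dimnames(rho) <- list(ids, ids)
  structure(list(rho = rho, n = sum(keep), neuron_ids = ids,
                 constant = constant),
            class = "coherence_matrix")
}

#' Threshold a coherence matrix into a functional graph
#'
#' Two neurons are functionally connected when their correlation
#' coefficient exceeds the threshold (0.45, the fixed empirical value used
#' for these maps) and, when the significance gate is enabled, the
#' conventional correlation t-test with `n - 2` degrees of freedom gives
#' p < 0.05. Only positive correlations above threshold form edges.
#'
#' @param C A [coherence_matrix()], or a plain symmetric numeric matrix
#'   (then `require_significance` must be `FALSE`).
#' @param threshold Correlation threshold in `[-1, 1]`.
#' @param require_significance Also require p < 0.05 from the correlation
#'   t-test for the trace length.
#' @param alpha Significance level for the gate.
#' @return An object of class `functional_graph`: `adjacency` (binary,
#'   symmetric, hollow), `m` (edge count), `K`, `threshold`.
#' @export
threshold_adjacency <- function(C, threshold = 0.45,
                                require_significance = FALSE,
                                alpha = 0.05) {
  if (is.matrix(C)) {
    if (require_significance)
      abort_bad_arg("C", "significance gate needs a coherence_matrix (sample size)")
    C <- structure(list(rho = C, n = NA_integer_,
                        neuron_ids = rownames(C) %||%
                          as.character(seq_len(nrow(C)))),
                   class = "coherence_matrix")
  }
  if (!inherits(C, "coherence_matrix"))
    abort_bad_arg("C", "must be a coherence_matrix or matrix")
  check_number(threshold, "threshold", lower = -1, upper = 1)
  rho <- C$rho
  A <- (rho > threshold) * 1
  if (require_significance) {
    n <- C$n
    r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    A <- A * (p < alpha)
  }
  diag(A) <- 0
  A <- A * (t(A) == A)  # defensive: keep symmetric
  dimnames(A) <- list(C$neuron_ids, C$neuron_ids)
  structure(list(adjacency = A, m = sum(A) / 2, K = nrow(A),
                 threshold = threshold),
            class = "functional_graph")
}

#' Construct a functional graph from an adjacency matrix
#'
#' @param A Binary symmetric adjacency matrix with zero diagonal.
#' @return A `functional_graph`.
#' @export
functional_graph <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    abort_bad_arg("A", "must be a square matrix")
  if (any(A != t(A))) abort_bad_arg("A", "must be symmetric")
  if (any(diag(A) != 0)) abort_bad_arg("A", "diagonal must be zero")
  if (!all(A %in% c(0, 1))) abort_bad_arg("A", "entries must be 0 or 1")
  structure(list(adjacency = A, m = sum(A) / 2, K = nrow(A),
                 threshold = NA_real_),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> K = %d nodes, m = %g edges, density %.4f\n",
              x$K, x$m, connectivity_density(x)))
  invisible(x)
}

#' Connectivity density
#'
#' Fraction of realized connections of an undirected network,
#' `2 m / (K (K - 1))`: 1 when every neuron is connected to every other.
#'
#' @param G A `functional_graph` (see [threshold_adjacency()]), or a list
#'   with `m` and `K`.
#' @return Density in `[0, 1]`.
#' @export
connectivity_density <- function(G) {
  K <- G$K; m <- G$m
  if (is.null(K) || K < 2) abort_bad_arg("G", "needs K >= 2 nodes")
  2 * m / (K * (K - 1))
}

#' Format a fraction as a percentage the way the source tables print it
#'
#' One decimal, truncated toward zero (so 0.025633 prints as 2.5, not 2.6).
#'
#' @param x Fraction in `[0, 1]`.
#' @return Percentage, one decimal.
#' @export
percent1 <- function(x) trunc(1000 * x) / 10

# breadth-first shortest path lengths from one source on an adjacency matrix
bfs_distances <- function(A, src) {
  K <- nrow(A)
  dist <- rep(Inf, K)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] != 0)
      nb <- nb[!is.finite(dist[nb])]
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

#' Global efficiency of a functional graph
#'
#' Inverse harmonic mean of the shortest path lengths:
#' `E = (1 / (K (K - 1))) * sum_{i != j} 1 / L_ij`, with unweighted
#' shortest paths from breadth-first search and `1 / L_ij = 0` for
#' disconnected pairs. 1 for a complete graph, 0 for an edgeless one; a
#' measure of the network's capacity for parallel information transfer.
#'
#' @param G A `functional_graph`.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(G) {
  A <- G$adjacency
  K <- nrow(A)
  if (is.null(K) || K < 2) abort_bad_arg("G", "needs K >= 2 nodes")
  total <- 0
  for (i in seq_len(K)) {
    d <- bfs_distances(A, i)
    d[i] <- Inf  # exclude self-pair
    total <- total + sum(1 / d[is.finite(d)])
  }
  total / (K * (K - 1))
}
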