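test_that("coherence matrix matches the printed-formula double loop", {
  set.seed(42)
  n <- 5000
  V <- cbind(rnorm(n), rnorm(n), rnorm(n))
  traces <- lapply(1:3, function(i) fl_trace(V[, i], neuron_id = paste0("n", i)))
  C <- coherence_matrix(traces)
  expect_lt(max(abs(C$rho - pearson_formula_oracle(V))), 1e-12)
  expect_equal(diag(C$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(C$rho, t(C$rho))
})

test_that("self and sign-flipped traces give +1 / -1 coherence", {
  x <- sin(seq(0, 20, length.out = 1000)) + rnorm(1000, 0, 0.1)
  traces <- list(fl_trace(x, neuron_id = "a"),
                 fl_trace(x, neuron_id = "a2"),
                 fl_trace(-x, neuron_id = "b"))
  C <- coherence_matrix(traces)
  expect_equal(C$rho["a", "a2"], 1, tolerance = 1e-12)
  expect_equal(C$rho["a", "b"], -1, tolerance = 1e-12)
})

test_that("constant traces are flagged and their correlations zeroed", {
  traces <- list(fl_trace(rnorm(500), neuron_id = "a"),
                 fl_trace(rep(2, 500), neuron_id = "flat"))
  expect_warning(C <- coherence_matrix(traces), "constant")
  expect_equal(C$rho["a", "flat"], 0)
  expect_true(C$constant[2])
})

test_that("thresholding counts edges and respects the significance gate", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- 0.5
  rho[2, 4] <- rho[4, 2] <- 0.46
  rho[3, 4] <- rho[4, 3] <- 0.1
  C <- structure(list(rho = rho, n = 1500,
                      neuron_ids = letters[1:4],
                      constant = rep(FALSE, 4)),
                 class = "coherence_matrix")
  G <- threshold_adjacency(C, 0.45)
  expect_equal(G$m, 3)
  expect_equal(threshold_adjacency(C, 0.89)$m, 1)
  expect_equal(threshold_adjacency(diag(4), 0.45)$m, 0)
  expect_error(threshold_adjacency(C, 1.2), "threshold")
  # with n = 3 samples nothing survives the t-test gate at alpha 0.05
  C$n <- 3
  expect_equal(threshold_adjacency(C, 0.45, require_significance = TRUE)$m, 0)
})

test_that("edge count is monotonically non-increasing in the threshold", {
  set.seed(99)
  x <- matrix(rnorm(16), 4)
  rho <- cor(rbind(x, x + matrix(rnorm(16, 0, 2), 4)))
  C <- structure(list(rho = rho, n = 8, neuron_ids = as.character(1:4),
                      constant = rep(FALSE, 4)),
                 class = "coherence_matrix")
  ms <- vapply(seq(-0.9, 0.9, by = 0.1),
               function(th) threshold_adjacency(C, th)$m, numeric(1))
  expect_true(all(diff(ms) <= 0))
})

test_that("connectivity density reproduces the worked field examples", {
  expect_equal(connectivity_density(list(K = 80, m = 134)), 268 / 6320)
  expect_equal(percent1(connectivity_density(list(K = 80, m = 134))), 4.2)
  expect_equal(connectivity_density(list(K = 80, m = 81)), 162 / 6320)
  expect_equal(percent1(connectivity_density(list(K = 80, m = 81))), 2.5)
  complete5 <- functional_graph(1 - diag(5))
  expect_equal(connectivity_density(complete5), 1)
  expect_error(connectivity_density(list(K = 1, m = 0)), "K >= 2")
})

test_that("global efficiency matches hand-enumerated and brute-force oracles", {
  A_path <- matrix(0, 4, 4)
  for (i in 1:3) A_path[i, i + 1] <- A_path[i + 1, i] <- 1
  # BFS distances {1,1,1,2,2,3} -> ordered-pair sum 2*(3 + 1 + 1/3) / 12
  expect_equal(global_efficiency(functional_graph(A_path)),
               2 * (3 + 1 + 1 / 3) / 12, tolerance = 1e-12)
  expect_equal(global_efficiency(functional_graph(1 - diag(6))), 1)
  expect_equal(global_efficiency(functional_graph(matrix(0, 5, 5))), 0)
  set.seed(7)
  for (rep in 1:25) {
    K <- sample(4:12, 1)
    A <- random_adjacency(K, runif(1, 0.1, 0.6))
    G <- functional_graph(A)
    expect_equal(global_efficiency(G), fw_efficiency_oracle(A),
                 tolerance = 1e-12)
    # independent library cross-check
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(global_efficiency(G), igraph::global_efficiency(ig),
                 tolerance = 1e-12)
  }
})

test_that("efficiency grows and metrics are permutation invariant", {
  set.seed(12)
  A <- random_adjacency(9, 0.2)
  G <- functional_graph(A)
  e0 <- global_efficiency(G)
  off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  add <- off[sample(nrow(off), 1), ]
  A2 <- A; A2[add[1], add[2]] <- A2[add[2], add[1]] <- 1
  expect_gte(global_efficiency(functional_graph(A2)), e0)
  p <- sample(9)
  Ap <- A[p, p]
  expect_equal(global_efficiency(functional_graph(Ap)), e0,
               tolerance = 1e-12)
  expect_equal(connectivity_density(functional_graph(Ap)),
               connectivity_density(G))
})

test_that("co-recruited populations are denser than segregated ones", {
  # two conditions exciting an overlapping vs disjoint neuron set
  make_pop <- function(p_multi, seed) {
    spec <- population_spec(n_neurons = 24, p_multimodal = p_multi,
                            p_unimodal = 1 - p_multi - 0.02,
                            p_nonparticipant = 0.02,
                            shared_mod_amplitude = 0.8, seed = seed)
    generate_population(spec, trace_noise_spec(), n_trials = 1)
  }
  density_of <- function(pop) {
    traces <- lapply(pop$traces$IV[[1]], remove_drift)
    C <- coherence_matrix(traces, window = pop$protocols$IV$stim_on)
    mean(vapply(c(0.1, 0.15, 0.2), function(th)
      connectivity_density(threshold_adjacency(C, th)), numeric(1)))
  }
  dens_overlap <- density_of(make_pop(0.9, 101))
  dens_disjoint <- density_of(make_pop(0.08, 102))
  expect_gt(dens_overlap, dens_disjoint)
})
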