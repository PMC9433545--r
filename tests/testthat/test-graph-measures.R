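test_that("closed-form values on canonical graphs", {
  K5 <- g_complete(5)
  D5 <- shortest_path_lengths(K5)
  expect_equal(degree_centrality(K5), rep(4L, 5))
  expect_equal(clustering_coefficient(K5)$Cp, 1)
  expect_equal(as.numeric(characteristic_path_length(D5)), 1)
  expect_equal(global_efficiency(D5), 1)
  expect_equal(local_efficiency(K5)$network, 1)
  expect_true(is.na(assortativity_degree(K5)))       # zero degree variance
  expect_equal(synchronization(g_complete(6)), 1)     # spectrum {0, n, ..., n}

  star <- g_star(5)
  expect_equal(betweenness_centrality(star), c(6, 0, 0, 0, 0))  # C(4,2)
  expect_equal(clustering_coefficient(star)$nodal, rep(0, 5))
  expect_equal(assortativity_degree(star), -1)
  expect_equal(local_efficiency(star)$nodal, rep(0, 5))

  P4 <- g_path(4)
  expect_equal(as.numeric(characteristic_path_length(shortest_path_lengths(P4))),
               10 / 6)
  P3 <- g_path(3)
  expect_equal(global_efficiency(shortest_path_lengths(P3)), 5 / 6)

  C4 <- g_cycle(4)
  expect_equal(synchronization(C4), 0.5)   # Laplacian spectrum {0, 2, 2, 4}
  expect_equal(betweenness_centrality(C4), rep(0.5, 4))
})

test_that("disconnected graphs are handled by the stated conventions", {
  # two disjoint triangles: Lp = 1 over reachable pairs, 9 pairs excluded
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  lp <- characteristic_path_length(shortest_path_lengths(A))
  expect_equal(as.numeric(lp), 1)
  expect_equal(attr(lp, "excluded_pairs"), 9)

  # two disjoint edges on 4 nodes: E_glob = 2/6
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- B[3, 4] <- B[4, 3] <- 1
  expect_equal(global_efficiency(shortest_path_lengths(B)), 1 / 3)

  expect_equal(synchronization(A), 0)
})

test_that("triangle plus pendant matches neighbour-pair enumeration", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1
  A[3, 4] <- A[4, 3] <- 1
  cc <- clustering_coefficient(A)$nodal
  expect_equal(cc, c(1, 1, 1 / 3, 0))
})

test_that("hierarchy exponent recovers exact power laws and flat profiles", {
  # build graphs only to define nodes; the fit is checked on synthetic (k, C)
  # via the regression the measure performs -- use the brute-force oracle on
  # real graphs instead for end-to-end checks
  set.seed(31)
  for (s in 1:5) {
    A <- o_random_graph(8, 0.6, 310 + s)
    expect_equal(hierarchy(A), o_hierarchy(A), tolerance = 1e-10)
  }
})

test_that("every measure equals its brute-force oracle on random graphs", {
  set.seed(32)
  n_checked <- 0
  for (s in 1:18) {
    n <- 5 + (s %% 5)
    p <- c(0.3, 0.5, 0.7)[1 + (s %% 3)]
    A <- o_random_graph(n, p, 5000 + s)
    if (sum(A) < 4) next
    D <- shortest_path_lengths(A)
    Do <- o_distances(A)
    expect_equal(D, Do, ignore_attr = TRUE)
    expect_equal(degree_centrality(A), as.integer(rowSums(A)))
    expect_equal(clustering_coefficient(A)$nodal, o_clustering(A),
                 tolerance = 1e-10)
    expect_equal(betweenness_centrality(A), o_betweenness(A),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(D), o_global_eff(Do), tolerance = 1e-10)
    expect_equal(nodal_efficiency(D), o_nodal_eff(Do), tolerance = 1e-10)
    expect_equal(local_efficiency(A)$nodal, o_local_eff(A), tolerance = 1e-10)
    expect_equal(is.na(assortativity_degree(A)), is.na(o_assortativity(A)))
    if (!is.na(o_assortativity(A))) {
      expect_equal(assortativity_degree(A), o_assortativity(A),
                   tolerance = 1e-10)
    }
    expect_equal(synchronization(A), o_synchronization(A), tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)
})

test_that("degree-preserving rewiring keeps the degree sequence exactly", {
  A <- make_group_graph(60, 6, 0.1, seed = 33)
  for (s in 1:10) {
    B <- rewire_degree_preserving(A, seed = 330 + s)
    expect_equal(rowSums(B), rowSums(A))
    expect_equal(sum(B), sum(A))
    expect_true(all(diag(B) == 0))
  }
  expect_identical(rewire_degree_preserving(A, n_swaps = 0, seed = 1), A)
})

test_that("randomization destroys lattice clustering", {
  A <- make_group_graph(60, 6, 0, seed = 34)   # ring lattice
  cp0 <- clustering_coefficient(A)$Cp
  cps <- vapply(1:20, function(s) {
    clustering_coefficient(rewire_degree_preserving(A, seed = 700 + s))$Cp
  }, 0)
  expect_true(all(cps < 0.5 * cp0))
})

test_that("small-world coefficients are 1 when the null equals the network", {
  # K8 admits no valid double-edge swap, so every null IS the network
  sw <- small_world_coefficients(g_complete(8), n_random = 5, seed = 35)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("Watts-Strogatz networks are small-world; random graphs are not", {
  A <- make_group_graph(116, 10, 0.1, seed = 36)
  sw <- small_world_coefficients(A, n_random = 20, seed = 37)
  expect_gt(sw$gamma, 1)
  expect_gt(sw$lambda, 0.9)
  expect_lt(sw$lambda, 1.2)
  expect_gt(sw$sigma, 1)

  # an Erdos-Renyi graph is its own null up to sampling error
  sigmas <- vapply(1:10, function(s) {
    R <- o_random_graph(60, 0.15, 900 + s)
    R <- largest <- R   # may be disconnected; handled internally
    small_world_coefficients(R, n_random = 10, seed = s)$sigma
  }, 0)
  expect_lt(abs(mean(sigmas) - 1), 0.1)
})

test_that("AUC over sparsity normalizes like an average", {
  sweep <- seq(0.1, 0.5, by = 0.1)
  expect_equal(auc_over_sparsity(rep(3.7, 5), sweep), 3.7)
  lin <- seq(2, 10, length.out = 5)
  expect_equal(auc_over_sparsity(lin, sweep), 6)   # (a + b) / 2
  set.seed(38)
  v <- runif(5)
  # independent trapezoid oracle
  o <- sum(diff(sweep) * (v[-5] + v[-1]) / 2) / 0.4
  expect_equal(auc_over_sparsity(v, sweep), o, tolerance = 1e-12)
  expect_error(auc_over_sparsity(v[1:3], sweep), "differ")
})

test_that("the per-subject metric table is complete and deterministic", {
  coh <- small_cohort()
  R <- pearson_connectivity(coh$subjects[[1]]$timeseries)
  sweep <- seq(0.2, 0.5, by = 0.15)
  nets <- sweep_networks(R, sweep)
  mt <- compute_metric_table(nets, sweep, n_random = 5, seed = 39,
                             subject_id = "s1")
  expect_named(mt$auc_global,
               c("Cp", "Lp", "global_efficiency", "local_efficiency",
                 "assortativity", "hierarchy", "synchronization",
                 "gamma", "lambda", "sigma"))
  expect_equal(dim(mt$nodal), c(3, 6, 116))
  expect_true(all(is.finite(mt$auc_nodal)))
  mt2 <- compute_metric_table(nets, sweep, n_random = 5, seed = 39,
                              subject_id = "s1")
  expect_identical(mt$auc_global, mt2$auc_global)

  # complete graphs at every density: unit rows
  ksweep <- c(0.3, 0.5)
  knets <- lapply(ksweep, function(d) g_complete(10))
  kt <- compute_metric_table(knets, ksweep, include_smallworld = FALSE)
  expect_equal(unname(kt$auc_global[c("Cp", "Lp", "global_efficiency")]),
               c(1, 1, 1))
})
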