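test_that("group graph generator: lattice limit, edge count, connectivity", {
  # p = 0: pure ring lattice, every node has degree k
  A0 <- make_group_graph(116, 10, 0, seed = 1)
  expect_true(all(rowSums(A0) == 10))
  expect_equal(sum(A0) / 2, 580)

  # rewiring never changes the edge count
  for (s in 1:5) {
    A <- make_group_graph(116, 10, 0.1, seed = s)
    expect_equal(sum(A) / 2, 580)
    expect_true(all(A == t(A)) && all(diag(A) == 0))
    D <- shortest_path_lengths(A)
    expect_true(all(is.finite(D)))   # connected by construction
  }
})

test_that("rewiring shortens paths while roughly preserving clustering", {
  # compare against the exact p = 0 lattice via the brute-force oracle
  L0 <- make_group_graph(20, 4, 0, seed = 2)
  lat_lp <- o_lp(o_distances(L0))
  lat_cp <- mean(o_clustering(L0))
  lps <- cps <- numeric(30)
  for (s in 1:30) {
    A <- make_group_graph(20, 4, 0.05, seed = 100 + s)
    lps[s] <- o_lp(o_distances(A))
    cps[s] <- mean(o_clustering(A))
  }
  expect_lt(mean(lps), lat_lp)
  # mild rewiring only nicks clustering on average (single draws vary more)
  expect_gt(mean(cps), 0.75 * lat_cp)
})

test_that("subject jitter preserves edge count and symmetry", {
  A <- make_group_graph(50, 6, 0.1, seed = 3)
  B <- jitter_graph(A, 0.05, seed = 4)
  expect_equal(sum(B), sum(A))
  expect_true(all(B == t(B)) && all(diag(B) == 0))
  expect_false(identical(A, B))
})

test_that("time-series generator recovers the population correlation", {
  # c = 0: independent columns
  A <- matrix(0, 6, 6)
  X <- simulate_timeseries(A, 0, 4000, seed = 5)
  R <- cor(X)
  expect_lt(max(abs(R[upper.tri(R)])), 0.06)

  # two-node closed form: population correlation of I + cA is exactly c
  A2 <- matrix(c(0, 1, 1, 0), 2)
  X2 <- simulate_timeseries(A2, 0.5, 10000, seed = 6)
  expect_lt(abs(cor(X2)[1, 2] - 0.5), 0.05)

  # determinism and unit sample variance
  expect_identical(X2, simulate_timeseries(A2, 0.5, 10000, seed = 6))
  expect_equal(unname(apply(X2, 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("time-series generator rejects an invalid covariance", {
  # star K_{1,11}: lambda_min(A) = -sqrt(11), so I + 0.5 A is indefinite
  expect_error(simulate_timeseries(g_star(12), 0.5, 100, seed = 1),
               "positive definite")
})

test_that("motion traces spike where recorded and are quiet otherwise", {
  m0 <- simulate_motion(226, 0, seed = 7)
  expect_length(m0$spike_volumes, 0)
  expect_true(all(framewise_displacement(m0$motion) < 0.5))

  m1 <- simulate_motion(226, 0.02, seed = 8)
  fd <- framewise_displacement(m1$motion)
  expect_true(all(fd[m1$spike_volumes] > 0.5))
})

test_that("spike count follows the stated Bernoulli-per-volume model", {
  counts <- vapply(1:200, function(s) {
    length(simulate_motion(226, 0.05, seed = 4000 + s)$spike_volumes)
  }, 0)
  # volumes 2..226 each spike with p = 0.05 -> Binomial(225, 0.05)
  expect_lt(abs(mean(counts) - 225 * 0.05), 0.8)
  expect_lt(abs(var(counts) - 225 * 0.05 * 0.95), 4)
})

test_that("default cohort has the stated structure", {
  coh <- small_cohort()
  expect_s3_class(coh, "synthetic_cohort")
  expect_length(coh$subjects, 12)
  expect_equal(sum(coh$phenotype$dx == 1), 6)
  s <- coh$subjects[[1]]
  expect_equal(dim(s$timeseries), c(226, 116))
  expect_equal(dim(s$motion), c(226, 6))
  expect_equal(colnames(s$timeseries)[9], "Frontal_Mid_Orb_L")
  # subject graphs keep the group edge count
  expect_true(all(coh$ground_truth$subject_edge_counts == 580))
  # ADHD IQ means injected lower
  ph <- coh$phenotype
  expect_lt(mean(ph$full_iq[ph$dx == 1]), mean(ph$full_iq[ph$dx == 0]))
})

test_that("full default cohort emulates the 56 + 56 design", {
  cfg <- simulation_config(seed = 99)
  expect_equal(cfg$n_per_group, 56L)
  expect_equal(cfg$n_roi, 116L)
  expect_equal(cfg$n_timepoints, 226L)
  expect_equal(cfg$tr_seconds, 2)
})

test_that("effect configuration lengthens ADHD ground-truth paths", {
  # group-graph path lengths computed by brute force before any simulation
  td <- make_group_graph(116, 10, 0.2, seed = derive_seed(17, 1))
  adhd <- make_group_graph(116, 10, 0.02, seed = derive_seed(17, 2))
  expect_gt(o_lp(o_distances(adhd)), o_lp(o_distances(td)))
})

test_that("cohort generation is seed-deterministic and file round-trips", {
  cfg <- simulation_config(n_per_group = 2, seed = 55)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects[[3]]$timeseries, b$subjects[[3]]$timeseries)
  expect_identical(a$phenotype, b$phenotype)

  dir <- tempfile("cohort")
  write_cohort(a, dir)
  rt <- read_cohort(dir)
  expect_equal(rt$phenotype$subject_id, a$phenotype$subject_id)
  expect_equal(as.vector(rt$subjects[[1]]$timeseries),
               as.vector(a$subjects[[1]]$timeseries), tolerance = 1e-6)
  expect_equal(dim(rt$subjects[[1]]$motion), c(226, 6))
  unlink(dir, recursive = TRUE)
})
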