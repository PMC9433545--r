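# Shared small-cohort fixtures, built once per test run.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(n_per_group = 6, seed = 301))
    }
    cache
  }
})

# fast global metrics (no null ensembles) on a reduced sweep
reduced_sweep <- seq(0.10, 0.50, by = 0.10)

global_aucs <- function(ts, sweep = reduced_sweep) {
  nets <- sweep_networks(pearson_connectivity(ts), sweep)
  vals <- sapply(nets, function(nw) {
    D <- shortest_path_lengths(nw)
    c(Cp = clustering_coefficient(nw)$Cp,
      Lp = as.numeric(characteristic_path_length(D)),
      global_efficiency = global_efficiency(D))
  })
  apply(vals, 1, auc_over_sparsity, sweep = sweep)
}

cohort_global_matrix <- function(cohort, sweep = reduced_sweep) {
  t(sapply(cohort$subjects, function(s) global_aucs(s$timeseries, sweep)))
}
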