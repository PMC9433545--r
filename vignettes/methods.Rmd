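---
title: "From regional BOLD time series to small-world statistics and a circularity audit: the adhdnet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{adhdnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`adhdnet` implements a complete graph-theoretical analysis of resting-state
functional connectivity for a two-group (ADHD vs typically developing)
case-control design, from regional time series to classifier performance
tables. The stages are:

1. **Time-series cleaning** (`preprocess_subject`): discard the first 10
   volumes, remove per-region linear trends, ideal band-pass 0.01-0.1 Hz,
   censor high-motion volumes by frame-wise displacement (FD) with linear
   interpolation, and regress out the Friston-24 motion expansion.
   Subjects with mean FD above 0.3 mm are excluded outright.
2. **Network construction** (`pearson_connectivity`,
   `threshold_by_density`): the 116 x 116 Pearson correlation matrix over
   AAL regions, binarized at fixed densities 10-50% in 1% steps
   (`density_sweep()`), giving each subject the same wiring cost at each
   density. Because edges are defined by a single descending ranking of the
   correlations, the 41 networks are nested.
3. **Graph measures** (`compute_metric_table`): per density, six nodal
   measures (degree, betweenness, clustering, nodal path length, nodal
   efficiency, nodal local efficiency) and ten global ones (Cp, Lp, global
   and local efficiency, assortativity, hierarchy, synchronization, and the
   small-world coefficients gamma, lambda, sigma). Each measure is averaged
   over the sweep by a normalized trapezoid (`auc_over_sparsity`), the
   threshold-free summary used by all downstream stages.
4. **Group statistics** (`group_compare`, `detect_hubs`): ANCOVA per
   measure with age, gender, mean FD and the three IQ scores as covariates,
   Benjamini-Hochberg FDR across measures; hubs are nodes whose group-mean
   betweenness exceeds the across-node mean by more than two across-node
   standard deviations.
5. **Classification** (`nested_cv_classify`, `circular_cv_classify`):
   706 features (10 global + 6 x 116 nodal AUC values), recursive feature
   elimination down to 12 features, and stratified 9-fold cross-validation
   of a linear SVM, a random forest and a gradient-boosting classifier,
   with ADHD as the positive class and metrics pooled over folds. The
   *circular* mode deliberately commits the audited mistake - selecting
   features on all subjects before cross-validation - to quantify the
   optimism it buys.

# The small-world statistics

With Cp the mean clustering coefficient and Lp the characteristic path
length (mean hop count over reachable pairs), the normalized coefficients
are

- gamma = Cp / C_rand,
- lambda = Lp / L_rand,
- sigma = gamma / lambda,

where C_rand and L_rand are means over an ensemble (default 100, and 20 in
the reduced test suites) of degree-preserving rewired null networks
(Markov chains of double-edge swaps, 10 x edge-count swap trials each). A
small-world network has gamma > 1, lambda near 1, and hence sigma > 1.
One source prints the ratio in (3) as delta while calling it sigma in the
text; the package uses sigma throughout.

Conventions for measures whose textbook definitions vary:

- **Path length on disconnected graphs.** At 10% density a 116-node binary
  network is frequently disconnected, so Lp averages over reachable pairs
  only and reports the number of excluded pairs; efficiencies handle
  unreachability natively (1/infinity = 0). gamma/lambda/sigma are computed
  on the largest connected component, with the coverage recorded.
- **Betweenness** is unnormalized (hub thresholds are set on that scale);
  a normalized variant is available by flag.
- **Assortativity** is the Pearson correlation of end-point degrees over
  both edge orientations (undefined when all degrees are equal),
  **hierarchy** is the exponent beta of C(k) ~ k^-beta fitted on nodes with
  degree >= 2 and positive clustering, and **synchronization** is the
  Laplacian eigenratio lambda_2 / lambda_max. These follow the conventions
  of the standard connectome toolboxes.
- **Thresholding** ranks signed correlations (strongest positive first) by
  default, with an absolute-value mode available; ties at the density
  cutoff break by (row, column) order so results are reproducible.
  A Fisher z-transform before thresholding would be rank-invariant and is
  therefore omitted.

# The synthetic cohort: what it emulates and what it does not

Real multi-site ADHD data cannot ship with a package, so every stage is
exercised against a generator (`simulate_cohort`) whose ground truth is
known and recoverable:

- **Topology.** Each group has a Watts-Strogatz group graph on 116 nodes
  with even lattice degree `ws_neighbors = 10` (580 edges, matching the
  10-17% density range where binary brain graphs are usually summarized).
  The TD-like group is rewired with probability 0.2, the ADHD-like group
  with 0.02; less rewiring means a more lattice-like graph with *longer*
  characteristic path length and lower global efficiency - the direction
  of the effect under study. Each subject's graph re-wires 2% of the group
  edges (edge count preserved) for idiosyncrasy.
- **No-effect cohorts share one graph.** When the two rewiring
  probabilities are equal the generator draws a single realized graph for
  both groups. With independently drawn graphs the groups would differ by
  an arbitrary realized-graph contrast shared by all subjects of a group,
  and subject-level tests would be anticonservative (about 28% of "null"
  cohorts produced an FDR discovery in pilot runs); with a shared graph
  the groups are exchangeable and the empirical false-positive rate is
  nominal. Equal rewiring probabilities are therefore the package's
  definition of "no injected topological effect".
- **Signal model.** T = 226 volumes (236 acquired minus 10 discarded) at
  TR = 2 s are drawn from a zero-mean Gaussian with covariance I + cA and
  standardized; the population correlation of an edge pair is c, so
  Pearson networks have an analytically known truth. The default coupling
  c = 0.15 is a typical resting-state edge correlation and lies safely
  inside the positive-definiteness region, which for these graphs is
  c < 1/|lambda_min(A)| (about 0.19). The bound c x max-degree < 1, often
  quoted as a sufficient condition, would cap c below the sample-noise
  floor 1/sqrt(T) and make the injected effect unrecoverable; the package
  therefore checks definiteness exactly (Cholesky) and redraws or rejects
  invalid configurations.
- **Covariates and motion.** Age matched (11.5 +/- 1.8 vs 11.9 +/- 2.2
  years), all three IQs lower in the ADHD-like group (e.g. full IQ 103.6
  vs 118.2), gender approximately 80% male, mean FD near 0.15 mm;
  motion traces are slow random walks plus Bernoulli(0.02 per volume)
  spikes built to exceed the 0.5 mm scrubbing threshold.

The generator does **not** model hemodynamics, scanner drift/physiological
noise spectra, spatial structure within regions, or site effects. A green
recovery test therefore establishes that the pipeline detects a known
topological contrast under Gaussian signal assumptions - not that it would
behave identically on scanner data.

# Numerical and design choices

- **FD** is the Power form: sum of absolute backward-differenced
  translations plus 50 mm times the summed rotation differences; the first
  volume has FD 0. Two thresholds coexist deliberately: scrubbing censors
  volumes with FD > 0.5 mm (window t-1..t+2), subject exclusion uses
  mean FD > 0.3 mm (strict inequality).
- **Band-pass** is an ideal rectangular mask on discrete Fourier
  frequencies (toolbox convention), exactly testable: an in-band on-grid
  sinusoid is retained, DC and out-of-band components are annihilated.
- **Pipeline order** is fixed and logged: discard, detrend, band-pass,
  scrub, nuisance regression.
- **Nuisance models**: none; Friston-24 (6 parameters, their one-lag
  backward differences, both squared); or Friston-24 plus the grand mean
  over regions as a global-signal proxy (WM/CSF signals do not exist at
  region level - a documented deviation from voxel-level practice).
- **Classifiers** are implemented in the package (no SVM or tree-ensemble
  package is available in the target environment): a dual
  coordinate-descent linear SVM (features standardized by training-fold
  statistics), bagged CART trees with sqrt(p) feature subsampling, and
  depth-2 logistic-loss gradient boosting (shrinkage 0.1, 100 rounds).
  RFE drops the least important 10% per iteration (|w| for the SVM,
  impurity reduction for the ensembles). Pooled-count metrics were chosen
  over fold-averaging for determinism; the ADHD class is positive.
- **Missing metric values** (e.g. assortativity on a degree-regular graph)
  are median-imputed inside each training fold only; the held-out fold
  reuses the training medians.
- **Seeds.** One master seed; every subject, density, null ensemble, fold
  and permutation derives its own 32-bit substream via `derive_seed`, so
  any unit can be reproduced in isolation.

# Scale reductions in the shipped test suites

The statistical acceptance suites state their thresholds at the original
scale but run reduced designs so the whole suite fits a desktop budget:
null ensembles of 20 (not 100) networks, density grids coarsened to 10%
steps, the type-I-error arm at 20 subjects per group (200 cohorts; the
nominal level does not depend on group size), and the permutation audit on
a reduced feature block (seven global measures plus a betweenness subset).
The recovery arm keeps the stated 56 + 56 design. None of the decision
thresholds (>= 80% power, <= 7.5% false-positive cohorts, nested accuracy
50 +/- 5%, circular strictly above nested) were altered.

# Known limitations

- Binary graphs only; weighted variants are out of scope.
- The phenotype covariate `mean_fd` is drawn from the stated group
  distributions, while scrubbing and exclusion use the FD measured on the
  simulated motion trace; the two are not coupled, so the covariate acts as
  a generic nuisance variable rather than a summary of the trace.
- The hub rule uses across-node dispersion of the group-mean centrality;
  the across-subject alternative is not implemented.
- ANCOVA assumes a linear covariate model; no site/batch structure.
- The circular-analysis audit quantifies selection-induced optimism only;
  other leakage routes (e.g. hyperparameter tuning on the full sample) are
  not modelled.
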