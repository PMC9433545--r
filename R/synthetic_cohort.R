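#' Simulation configuration for a two-group synthetic cohort
#'
#' The defaults state the cohort the downstream analyses expect: two groups
#' of 56 children, 116 AAL regions, 226 retained volumes at TR = 2 s (236
#' acquired minus 10 discarded). Group topology is Watts-Strogatz: both
#' groups share the lattice degree `ws_neighbors`; the comparison group
#' ("TD-like") is rewired more than the clinical group ("ADHD-like"), so the
#' clinical group keeps longer characteristic path length and lower global
#' efficiency -- the direction of the effect under study.
#'
#' @param n_per_group subjects per group (default 56)
#' @param n_roi number of regions (default 116)
#' @param n_timepoints retained volumes (default 226)
#' @param tr_seconds repetition time in seconds (default 2)
#' @param ws_neighbors even lattice degree k of the base small-world graph
#'   (default 10)
#' @param ws_rewire_td rewiring probability of the TD group graph (default 0.2)
#' @param ws_rewire_adhd rewiring probability of the ADHD group graph
#'   (default 0.02; smaller than `ws_rewire_td` lengthens ADHD paths)
#' @param edge_coupling correlation strength c of the signal covariance
#'   I + c*A (default 0.15, a typical resting-state edge correlation;
#'   I + c*A must be positive definite, which for degree-10 small-world
#'   graphs holds up to c of roughly 0.19)
#' @param subject_edge_jitter fraction of group-graph edges independently
#'   rewired per subject, edge count preserved (default 0.02)
#' @param covariate_params list of group-wise covariate distributions; see
#'   Details. Defaults mirror the demographic table of the cohort emulated:
#'   matched age (11.5 +/- 2 y), lower IQs in the ADHD group
#'   (full 103.55 vs 118.2 etc.), male proportion ~0.8, mean FD near 0.15 mm.
#' @param motion_spike_rate per-volume probability of a high-motion spike
#'   (default 0.02)
#' @param seed integer master seed
#'
#' @details `covariate_params` is a list with elements `td` and `adhd`, each
#'   a list with `age = c(mean, sd)`, `verbal_iq`, `performance_iq`,
#'   `full_iq`, `fd` (all `c(mean, sd)`) and `p_male` (scalar).
#'
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_per_group = 56L,
                              n_roi = 116L,
                              n_timepoints = 226L,
                              tr_seconds = 2.0,
                              ws_neighbors = 10L,
                              ws_rewire_td = 0.2,
                              ws_rewire_adhd = 0.02,
                              edge_coupling = 0.15,
                              subject_edge_jitter = 0.02,
                              covariate_params = NULL,
                              motion_spike_rate = 0.02,
                              seed = 1L) {
  stopifnot_scalar_count(n_per_group, "n_per_group")
  stopifnot_scalar_count(n_roi, "n_roi")
  stopifnot_scalar_count(n_timepoints, "n_timepoints")
  if (ws_neighbors %% 2 != 0) stop("ws_neighbors must be even")
  if (n_roi < ws_neighbors + 1) stop("n_roi must exceed ws_neighbors")
  for (p in c(ws_rewire_td, ws_rewire_adhd, subject_edge_jitter,
              motion_spike_rate)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (is.null(covariate_params)) {
    covariate_params <- list(
      td = list(age = c(11.51, 1.77), verbal_iq = c(120.9, 13.26),
                performance_iq = c(110.93, 15.03), full_iq = c(118.2, 13.46),
                fd = c(0.1434, 0.058), p_male = 44 / 56),
      adhd = list(age = c(11.86, 2.21), verbal_iq = c(107.48, 15.25),
                  performance_iq = c(98.43, 11.86), full_iq = c(103.55, 12.63),
                  fd = c(0.152, 0.046), p_male = 49 / 56)
    )
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_roi = as.integer(n_roi),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 ws_neighbors = as.integer(ws_neighbors),
                 ws_rewire_td = ws_rewire_td,
                 ws_rewire_adhd = ws_rewire_adhd,
                 edge_coupling = edge_coupling,
                 subject_edge_jitter = subject_edge_jitter,
                 covariate_params = covariate_params,
                 motion_spike_rate = motion_spike_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Connected Watts-Strogatz group graph
#'
#' Ring lattice on `n_roi` nodes of even degree `k`, each edge's far endpoint
#' rewired with probability `p_rewire` to a uniformly chosen non-neighbor.
#' Redrawn (bounded retries) until connected, so path-based measures are
#' defined everywhere. Edge count is exactly n*k/2 regardless of rewiring.
#'
#' @param n_roi node count
#' @param k even lattice degree
#' @param p_rewire rewiring probability
#' @param seed integer seed
#' @param max_retries connectivity retries before giving up (default 50)
#' @return n x n binary symmetric adjacency matrix
#' @export
make_group_graph <- function(n_roi, k, p_rewire, seed, max_retries = 50L) {
  if (k %% 2 != 0) stop("k must be even")
  if (k >= n_roi) stop("k must be smaller than n_roi")
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      g <- igraph::sample_smallworld(dim = 1, size = n_roi, nei = k / 2,
                                     p = p_rewire, loops = FALSE,
                                     multiple = FALSE)
      if (igraph::is_connected(g)) {
        A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
        dimnames(A) <- NULL
        storage.mode(A) <- "double"
        return(A)
      }
    }
    stop("could not draw a connected small-world graph in ", max_retries,
         " tries; parameters are degenerate")
  })
}

#' Per-subject graph: jittered copy of the group graph
#'
#' Rewires a fraction of the group graph's edges by degree-agnostic edge
#' replacement (delete a random edge, add a random non-edge), preserving the
#' edge count exactly. Models subject-level idiosyncrasy around a shared
#' group topology.
#'
#' @param A group adjacency matrix
#' @param jitter fraction of edges to move
#' @param seed integer seed
#' @return adjacency matrix with the same edge count
#' @export
jitter_graph <- function(A, jitter, seed) {
  if (jitter <= 0) return(A)
  with_seed(seed, {
    n <- nrow(A)
    ut <- which(upper.tri(A))
    edges <- ut[A[ut] == 1]
    nonedges <- ut[A[ut] == 0]
    m <- max(0L, round(jitter * length(edges)))
    m <- min(m, length(edges), length(nonedges))
    if (m == 0L) return(A)
    drop <- sample(edges, m)
    add <- sample(nonedges, m)
    B <- A
    B[drop] <- 0
    B[add] <- 1
    B[lower.tri(B)] <- 0
    B <- B + t(B)
    diag(B) <- 0
    B
  })
}

#' Simulate ROI time series with known population correlation structure
#'
#' Draws T observations from a zero-mean multivariate normal with covariance
#' I + c*A, then standardizes each column to zero mean and unit sample
#' variance. The population correlation of an adjacent pair is c (exactly,
#' for an isolated edge), so downstream Pearson networks have a recoverable
#' truth.
#'
#' @param subject_graph binary adjacency matrix
#' @param c coupling strength; c * max degree must be < 1 so that I + c*A is
#'   positive definite (Gershgorin bound)
#' @param T number of time points
#' @param seed integer seed
#' @return T x n_roi numeric matrix
#' @export
simulate_timeseries <- function(subject_graph, c, T, seed) {
  A <- subject_graph
  n <- nrow(A)
  # exact positive-definiteness requirement: c < 1 / |lambda_min(A)|.
  # (The Gershgorin bound c * maxdeg < 1 is sufficient but far too
  # conservative for lattice-like graphs, whose smallest eigenvalue is
  # much larger than -maxdeg; the Cholesky below is the authoritative
  # check and rejects any invalid pair with a diagnostic.)
  S <- diag(n) + c * A
  ch <- tryCatch(chol(S), error = function(e) {
    stop("covariance I + c*A is not positive definite: ",
         conditionMessage(e))
  })
  with_seed(seed, {
    Z <- matrix(stats::rnorm(T * n), nrow = T, ncol = n)
    X <- Z %*% ch
    X <- scale(X)            # unit sample variance per column
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    X
  })
}

#' Simulate a 6-parameter rigid-body motion trace
#'
#' Smooth low-amplitude drift (a slow random walk) plus single-volume spikes
#' large enough that the frame-wise displacement at each spike volume exceeds
#' the 0.5 mm scrubbing threshold. Spike volumes are Bernoulli(spike_rate)
#' over volumes 2..T (volume 1 has FD 0 by definition).
#'
#' @param T volumes
#' @param spike_rate per-volume spike probability
#' @param seed integer seed
#' @return list: `motion` (T x 6 matrix; 3 translations mm, 3 rotations rad),
#'   `spike_volumes` (integer vector of 1-based spike indices)
#' @export
simulate_motion <- function(T, spike_rate, seed) {
  with_seed(seed, {
    drift_t <- apply(matrix(stats::rnorm(T * 3, sd = 0.005), T, 3), 2, cumsum)
    drift_r <- apply(matrix(stats::rnorm(T * 3, sd = 1e-4), T, 3), 2, cumsum)
    motion <- cbind(drift_t, drift_r)
    spikes <- which(stats::runif(T) < spike_rate)
    spikes <- spikes[spikes > 1]          # FD of volume 1 is defined as 0
    for (s in spikes) {
      # single-volume translation excursion of 0.8 mm in x: FD > 0.5 at s
      motion[s, 1] <- motion[s, 1] + 0.8
    }
    list(motion = motion, spike_volumes = spikes)
  })
}

#' Simulate covariates for one group
#' @keywords internal
simulate_covariates <- function(n, params, seed) {
  with_seed(seed, {
    data.frame(
      age = stats::rnorm(n, params$age[1], params$age[2]),
      gender = as.integer(stats::runif(n) < params$p_male),
      verbal_iq = stats::rnorm(n, params$verbal_iq[1], params$verbal_iq[2]),
      performance_iq = stats::rnorm(n, params$performance_iq[1],
                                    params$performance_iq[2]),
      full_iq = stats::rnorm(n, params$full_iq[1], params$full_iq[2]),
      mean_fd = pmax(0.02, stats::rnorm(n, params$fd[1], params$fd[2]))
    )
  })
}

#' Simulate a complete two-group cohort
#'
#' Draws one group graph per group, jitters it per subject, simulates time
#' series, motion traces and covariates, and (optionally) writes the on-disk
#' cohort: per-subject time-series TSVs, motion text files, a phenotype CSV
#' and a ground-truth JSON.
#'
#' @param config a [simulation_config()]
#' @param out_dir directory to write the cohort to, or `NULL` to keep
#'   everything in memory
#' @return list of class `synthetic_cohort`: `subjects` (list with
#'   `subject_id`, `group`, `timeseries`, `motion`, `graph`, `spike_volumes`),
#'   `phenotype` (data.frame), `ground_truth` (group graphs, per-subject
#'   graphs, injected effects, seeds)
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- aal116()$label[seq_len(config$n_roi)]
  if (config$n_roi > 116) {
    labels <- c(aal116()$label, paste0("ROI_", 117:config$n_roi))[
      seq_len(config$n_roi)]
  }
  groups <- list(td = config$ws_rewire_td, adhd = config$ws_rewire_adhd)
  pd_ok <- function(A, margin = 0.02) {
    # positive definite with a little headroom for subject-level jitter
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    1 + config$edge_coupling * min(ev) > margin
  }
  draw_group <- function(p_rewire, tag) {
    for (try in 0:19) {
      A <- make_group_graph(config$n_roi, config$ws_neighbors, p_rewire,
                            derive_seed(config$seed, tag, try))
      if (pd_ok(A)) return(A)
    }
    stop("no positive-definite covariance I + c*A at edge_coupling = ",
         config$edge_coupling, "; lower it or ws_neighbors")
  }
  # The injected topological effect IS the difference between the two group
  # graphs. When the rewiring probabilities are equal no effect is injected,
  # so both groups share one realized graph; otherwise each group's subjects
  # would still be clustered on an arbitrary graph difference and group
  # exchangeability (the null contract) would not hold at subject level.
  if (config$ws_rewire_td == config$ws_rewire_adhd) {
    shared <- draw_group(config$ws_rewire_td, 1)
    group_graphs <- list(td = shared, adhd = shared)
  } else {
    group_graphs <- list(td = draw_group(config$ws_rewire_td, 1),
                         adhd = draw_group(config$ws_rewire_adhd, 2))
  }
  cov_td <- simulate_covariates(config$n_per_group,
                                config$covariate_params$td,
                                derive_seed(config$seed, 3))
  cov_adhd <- simulate_covariates(config$n_per_group,
                                  config$covariate_params$adhd,
                                  derive_seed(config$seed, 4))
  subjects <- vector("list", 2L * config$n_per_group)
  pheno <- NULL
  idx <- 0L
  for (g in c("td", "adhd")) {
    gi <- if (g == "td") 0L else 1L
    covs <- if (g == "td") cov_td else cov_adhd
    for (i in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("sub-%s%03d", toupper(g), i)
      # redraw the subject jitter (bounded) if it breaks positive
      # definiteness of I + c*A
      sg <- NULL
      for (try in 0:19) {
        cand <- jitter_graph(group_graphs[[g]], config$subject_edge_jitter,
                             derive_seed(config$seed, 10, gi, i, try))
        if (pd_ok(cand, margin = 0)) {
          sg <- cand
          break
        }
      }
      if (is.null(sg)) {
        stop("subject ", sid, ": no jitter draw kept I + c*A positive ",
             "definite; lower edge_coupling")
      }
      ts <- simulate_timeseries(sg, config$edge_coupling,
                                config$n_timepoints,
                                derive_seed(config$seed, 11, gi, i))
      colnames(ts) <- labels
      mo <- simulate_motion(config$n_timepoints, config$motion_spike_rate,
                            derive_seed(config$seed, 12, gi, i))
      subjects[[idx]] <- list(subject_id = sid, group = g,
                              timeseries = ts, motion = mo$motion,
                              spike_volumes = mo$spike_volumes, graph = sg)
      pheno <- rbind(pheno, data.frame(subject_id = sid, dx = gi, covs[i, ],
                                       row.names = NULL))
    }
  }
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  gt <- list(
    group_graphs = lapply(group_graphs, adjacency_to_edgelist),
    subject_edge_counts = vapply(subjects, function(s) sum(s$graph) / 2, 0),
    injected_effects = list(
      ws_rewire = c(td = config$ws_rewire_td, adhd = config$ws_rewire_adhd),
      edge_coupling = config$edge_coupling,
      iq_shift = config$covariate_params$td$full_iq[1] -
        config$covariate_params$adhd$full_iq[1]),
    seed = config$seed
  )
  cohort <- structure(list(subjects = subjects, phenotype = pheno,
                           ground_truth = gt, config = config),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

adjacency_to_edgelist <- function(A) {
  ij <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  data.frame(a = ij[, 1], b = ij[, 2])
}

#' Write a synthetic cohort to disk
#'
#' TSV time series (header of ROI labels), whitespace-delimited motion text
#' (SPM realignment dialect), phenotype CSV and ground-truth JSON.
#'
#' @param cohort a `synthetic_cohort`
#' @param out_dir output directory (created if absent)
#' @return `out_dir`, invisibly
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(out_dir, "timeseries")
  mo_dir <- file.path(out_dir, "motion")
  dir.create(ts_dir, showWarnings = FALSE)
  dir.create(mo_dir, showWarnings = FALSE)
  for (s in cohort$subjects) {
    fts <- file.path(ts_dir, paste0(s$subject_id, "_roi.tsv"))
    ok <- tryCatch({
      utils::write.table(s$timeseries, fts, sep = "\t", row.names = FALSE,
                         col.names = TRUE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("failed writing ", fts, ": ", conditionMessage(ok))
    utils::write.table(format(s$motion, digits = 8),
                       file.path(mo_dir, paste0(s$subject_id, "_motion.txt")),
                       sep = " ", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  utils::write.csv(cohort$phenotype, file.path(out_dir, "phenotype.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()] (or real data in that dialect)
#'
#' @param dir cohort directory
#' @return `synthetic_cohort`-shaped list (without ground truth unless the
#'   JSON is present)
#' @export
read_cohort <- function(dir) {
  pheno <- utils::read.csv(file.path(dir, "phenotype.csv"),
                           stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(pheno)), function(i) {
    sid <- pheno$subject_id[i]
    ts <- as.matrix(utils::read.delim(
      file.path(dir, "timeseries", paste0(sid, "_roi.tsv")),
      check.names = FALSE))
    mo_path <- file.path(dir, "motion", paste0(sid, "_motion.txt"))
    mo <- if (file.exists(mo_path)) {
      as.matrix(utils::read.table(mo_path))
    } else NULL
    list(subject_id = sid, group = if (pheno$dx[i] == 1) "adhd" else "td",
         timeseries = ts, motion = mo)
  })
  names(subjects) <- pheno$subject_id
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
  structure(list(subjects = subjects, phenotype = pheno, ground_truth = gt),
            class = "synthetic_cohort")
}
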