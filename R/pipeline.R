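#' Run the full analysis on a cohort
#'
#' Orchestrates preprocess -> Pearson connectivity -> density sweep ->
#' graph measures -> covariate-adjusted group statistics and hub detection
#' -> cross-validated classification, on a synthetic or ingested cohort.
#' Every stage is a package function; this driver only wires them together
#' and records seeds, so a stage can be re-run in isolation.
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()] or
#'   [read_cohort()])
#' @param preprocess run the time-series cleaning stage (set FALSE when the
#'   input is already clean, e.g. for fast simulation studies)
#' @param pre_config a [preprocess_config()]
#' @param sweep density sweep (default [density_sweep()])
#' @param n_random null-ensemble size for small-world coefficients
#' @param include_smallworld compute gamma/lambda/sigma (needs null
#'   ensembles; the expensive part)
#' @param classifiers subset of c("gb", "rf", "svm")
#' @param modes subset of c("nested", "circular")
#' @param cv a [cv_config()]
#' @param hub_criterion "betweenness" (default) or "degree"
#' @param seed master seed
#' @return list of class `cohort_analysis`: `metric_tables`, `features`,
#'   `group_stats`, `hubs` (per group), `classification` (per classifier x
#'   mode), `exclusions`, `qc`, `seed`
#' @export
run_cohort_analysis <- function(cohort,
                                preprocess = TRUE,
                                pre_config = preprocess_config(),
                                sweep = density_sweep(),
                                n_random = 100L,
                                include_smallworld = TRUE,
                                classifiers = c("gb", "rf", "svm"),
                                modes = c("nested", "circular"),
                                cv = cv_config(),
                                hub_criterion = "betweenness",
                                seed = 1L) {
  pheno <- cohort$phenotype
  qc <- list()
  excluded <- character(0)
  metric_tables <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    ts <- s$timeseries
    if (preprocess) {
      pp <- preprocess_subject(ts, s$motion, pre_config)
      qc[[s$subject_id]] <- pp$qc
      if (!pp$qc$keep) {
        excluded <- c(excluded, s$subject_id)
        next
      }
      ts <- pp$timeseries
    }
    R <- pearson_connectivity(ts)
    nets <- sweep_networks(R, sweep)
    metric_tables[[s$subject_id]] <-
      compute_metric_table(nets, sweep, n_random = n_random,
                           seed = derive_seed(seed, 20, i),
                           include_smallworld = include_smallworld,
                           subject_id = s$subject_id)
  }
  if (length(metric_tables) < 4) stop("too few subjects survived QC")
  pheno <- pheno[pheno$subject_id %in% names(metric_tables), ]
  metric_tables <- metric_tables[pheno$subject_id]
  feats <- assemble_features(metric_tables)
  labels <- pheno$dx[match(feats$subject_ids, pheno$subject_id)]
  covars <- pheno[match(feats$subject_ids, pheno$subject_id),
                  c("age", "gender", "mean_fd", "verbal_iq",
                    "performance_iq", "full_iq")]
  glob_cols <- grep("^global__", colnames(feats$X), value = TRUE)
  stats_tab <- group_compare(feats$X[, glob_cols, drop = FALSE], labels,
                             covars)
  roi_labels <- aal116()$label[seq_len(ncol(metric_tables[[1]]$auc_nodal))]
  crit_metric <- if (hub_criterion == "degree") "degree" else "betweenness"
  hub_block <- feats$X[, paste0(crit_metric, "__", roi_labels),
                       drop = FALSE]
  hubs <- list(
    td = detect_hubs(hub_block[labels == 0, , drop = FALSE],
                     criterion = hub_criterion, roi_labels = roi_labels),
    adhd = detect_hubs(hub_block[labels == 1, , drop = FALSE],
                       criterion = hub_criterion, roi_labels = roi_labels))
  classification <- list()
  for (m in classifiers) {
    for (mode in modes) {
      key <- paste(m, mode, sep = "_")
      classification[[key]] <- if (mode == "nested") {
        nested_cv_classify(feats, labels, cv, m)
      } else {
        circular_cv_classify(feats, labels, cv, m)
      }
    }
  }
  structure(list(metric_tables = metric_tables, features = feats,
                 labels = labels, group_stats = stats_tab, hubs = hubs,
                 classification = classification, exclusions = excluded,
                 qc = qc, sweep = sweep, seed = seed),
            class = "cohort_analysis")
}

#' Summarize a cohort analysis as printable tables
#'
#' @param analysis a `cohort_analysis`
#' @return list: `group_stats` (data.frame), `hub_counts`,
#'   `classification` (data.frame: classifier, mode, five metrics)
#' @export
summarize_analysis <- function(analysis) {
  cls <- do.call(rbind, lapply(analysis$classification, function(r) {
    data.frame(classifier = toupper(r$classifier), mode = r$mode,
               t(round(r$metrics, 1)), row.names = NULL)
  }))
  list(group_stats = analysis$group_stats,
       hub_counts = vapply(analysis$hubs,
                           function(h) length(h$hub_nodes), 0L),
       classification = cls)
}
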