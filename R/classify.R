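#' Assemble the subjects x features matrix from per-subject metric tables
#'
#' Deterministic column order: the global AUC-over-sparsity measures first,
#' then one block per nodal measure with ROIs in atlas order. Column names
#' are `global__<metric>` and `<metric>__<roi_label>`, so every feature is
#' traceable to its (measure, region) pair. Undefined entries (e.g.
#' assortativity on a degenerate graph) are left as NA here; imputation is
#' the cross-validation loop's job so that test folds never leak into
#' training medians.
#'
#' @param metric_tables list of `metric_table`, one per subject
#' @param roi_labels node labels (default AAL-116)
#' @return list of class `feature_matrix`: `X` (matrix), `subject_ids`
#' @export
assemble_features <- function(metric_tables, roi_labels = NULL) {
  stopifnot(length(metric_tables) > 0)
  n_roi <- ncol(metric_tables[[1]]$auc_nodal)
  if (is.null(roi_labels)) {
    roi_labels <- if (n_roi <= 116) aal116()$label[seq_len(n_roi)] else
      paste0("ROI_", seq_len(n_roi))
  }
  gnames <- names(metric_tables[[1]]$auc_global)
  cols <- c(paste0("global__", gnames),
            unlist(lapply(rownames(metric_tables[[1]]$auc_nodal),
                          function(m) paste0(m, "__", roi_labels))))
  rows <- lapply(metric_tables, function(mt) {
    c(mt$auc_global, as.vector(t(mt$auc_nodal)))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- cols
  rownames(X) <- vapply(metric_tables, function(mt) mt$subject_id, "")
  all_missing <- apply(X, 1, function(r) all(is.na(r)))
  if (any(all_missing)) {
    warning("excluding subject(s) with all-missing metrics: ",
            paste(rownames(X)[all_missing], collapse = ", "))
    X <- X[!all_missing, , drop = FALSE]
  }
  structure(list(X = X, subject_ids = rownames(X)), class = "feature_matrix")
}

impute_median <- function(X, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(X, 2, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[j]
  }
  list(X = X, medians = medians)
}

#' Recursive feature elimination
#'
#' Fits the chosen classifier on the current feature set, ranks features by
#' the model's own importance (|w| for the linear SVM, impurity reduction
#' for the tree ensembles), drops the lowest `rfe_step` fraction, and
#' repeats until `n_keep` features remain.
#'
#' @param X training-rows-only feature matrix (no NAs)
#' @param y training labels
#' @param model "svm", "rf" or "gb"
#' @param n_keep number of features to retain
#' @param rfe_step fraction of current features dropped per iteration
#'   (default 0.1)
#' @param seed integer seed
#' @return list: `selected` (column names, in original order),
#'   `elimination_order` (first-dropped first)
#' @export
rfe_select <- function(X, y, model, n_keep, rfe_step = 0.1, seed = 1L) {
  X <- as.matrix(X)
  if (n_keep >= ncol(X)) {
    return(list(selected = colnames(X), elimination_order = character(0)))
  }
  if (n_keep < 1) stop("n_keep must be at least 1")
  current <- colnames(X)
  dropped <- character(0)
  it <- 0L
  while (length(current) > n_keep) {
    it <- it + 1L
    cl <- fit_classifier(model, X[, current, drop = FALSE], y,
                         seed = derive_seed(seed, it))
    n_drop <- max(1L, floor(rfe_step * length(current)))
    n_drop <- min(n_drop, length(current) - n_keep)
    ord <- order(cl$importance)      # lowest importance first; ties by index
    out <- current[ord[seq_len(n_drop)]]
    dropped <- c(dropped, out)
    current <- setdiff(current, out)
  }
  list(selected = colnames(X)[colnames(X) %in% current],
       elimination_order = dropped)
}

#' Five confusion-matrix performance metrics, in percent
#'
#' ADHD is the positive class: accuracy = (TP+TN)/n, sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV =
#' TN/(TN+FN). A metric with a zero denominator is reported as NA.
#'
#' @param TP,FN,FP,TN confusion counts
#' @return named numeric vector (percent)
#' @export
metrics_from_confusion <- function(TP, FN, FP, TN) {
  TP <- unname(TP); FN <- unname(FN); FP <- unname(FP); TN <- unname(TN)
  n <- TP + FN + FP + TN
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(accuracy = rate(TP + TN, n),
    sensitivity = rate(TP, TP + FN),
    specificity = rate(TN, TN + FP),
    ppv = rate(TP, TP + FP),
    npv = rate(TN, TN + FN))
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validation configuration
#'
#' @param k folds (default 9)
#' @param n_selected_features features kept by RFE (default 12)
#' @param rfe_step fraction dropped per RFE iteration (default 0.1)
#' @param stratified stratify folds by class (default TRUE)
#' @param seed integer seed
#' @return object of class `cv_config`
#' @export
cv_config <- function(k = 9L, n_selected_features = 12L, rfe_step = 0.1,
                      stratified = TRUE, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (n_selected_features < 1) stop("n_selected_features must be >= 1")
  structure(list(k = as.integer(k),
                 n_selected_features = as.integer(n_selected_features),
                 rfe_step = rfe_step, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

cv_classify <- function(features, labels, config, model, circular) {
  X <- if (inherits(features, "feature_matrix")) features$X else
    as.matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stop("labels and feature rows differ")
  if (length(unique(y)) != 2) stop("need two classes")
  fold <- if (config$stratified) {
    stratified_folds(y, config$k, config$seed)
  } else {
    with_seed(config$seed, sample(rep_len(seq_len(config$k), length(y))))
  }
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2)) {
    stop("a fold contains a single class; use stratified folds or fewer folds")
  }
  selected_global <- NULL
  if (circular) {
    # the audited mistake: impute + select once, on ALL subjects
    imp <- impute_median(X)
    sel <- rfe_select(imp$X, y, model, config$n_selected_features,
                      config$rfe_step, seed = derive_seed(config$seed, 999))
    selected_global <- sel$selected
  }
  counts <- c(TP = 0L, FN = 0L, FP = 0L, TN = 0L)
  per_fold <- list()
  selected_per_fold <- list()
  for (f in seq_len(config$k)) {
    tr <- fold != f
    te <- !tr
    imp <- impute_median(X[tr, , drop = FALSE])
    Xtr <- imp$X
    Xte <- impute_median(X[te, , drop = FALSE], imp$medians)$X
    if (circular) {
      sel <- selected_global
    } else {
      sel <- rfe_select(Xtr, y[tr], model, config$n_selected_features,
                        config$rfe_step,
                        seed = derive_seed(config$seed, f))$selected
    }
    cl <- fit_classifier(model, Xtr[, sel, drop = FALSE], y[tr],
                         seed = derive_seed(config$seed, 100, f))
    pred <- cl$predict(Xte[, sel, drop = FALSE])
    tp <- sum(pred == 1 & y[te] == 1)
    fn <- sum(pred == 0 & y[te] == 1)
    fp <- sum(pred == 1 & y[te] == 0)
    tn <- sum(pred == 0 & y[te] == 0)
    counts <- counts + c(TP = tp, FN = fn, FP = fp, TN = tn)
    per_fold[[f]] <- c(TP = tp, FN = fn, FP = fp, TN = tn)
    selected_per_fold[[f]] <- sel
  }
  structure(list(classifier = model,
                 mode = if (circular) "circular" else "nested",
                 counts = counts,
                 metrics = metrics_from_confusion(counts["TP"], counts["FN"],
                                                  counts["FP"], counts["TN"]),
                 per_fold = per_fold,
                 selected_features = selected_per_fold,
                 config = config),
            class = "classification_report")
}

#' Nested (non-circular) cross-validated classification
#'
#' For each of k stratified folds, median imputation and recursive feature
#' elimination are run on the training fold only; the held-out fold is
#' predicted once. Confusion counts are pooled across folds and the five
#' performance metrics computed from the pooled counts, with ADHD as the
#' positive class.
#'
#' @param features `feature_matrix` or plain matrix
#' @param labels 0 (TD) / 1 (ADHD)
#' @param config a [cv_config()]
#' @param model "svm", "rf" or "gb"
#' @return `classification_report`
#' @export
nested_cv_classify <- function(features, labels, config = cv_config(),
                               model = c("gb", "rf", "svm")) {
  cv_classify(features, labels, config, match.arg(model), circular = FALSE)
}

#' Circular-analysis variant: feature selection on all subjects first
#'
#' Reproduces the audited mistake: RFE (and imputation medians for
#' selection) run once on the full sample before cross-validation, then the
#' same folds are evaluated on the pre-selected columns. Reported metrics
#' are optimistically biased relative to [nested_cv_classify()].
#'
#' @inheritParams nested_cv_classify
#' @return `classification_report` with `mode = "circular"`
#' @export
circular_cv_classify <- function(features, labels, config = cv_config(),
                                 model = c("gb", "rf", "svm")) {
  cv_classify(features, labels, config, match.arg(model), circular = TRUE)
}
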