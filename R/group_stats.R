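#' Pooled-variance two-sample t statistic
#'
#' Student t for group2 - group1 from summary statistics (means, SDs, group
#' sizes), matching how demographic tables report it. With equal n the
#' pooled form coincides with the unequal-variance statistic. Also callable
#' on raw vectors via [two_sample_t_raw()].
#'
#' @param mean1,sd1,n1 group 1 summaries
#' @param mean2,sd2,n2 group 2 summaries
#' @return list: `t`, `df`, `p` (two-sided)
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need at least 2 per group")
  if (sd1 <= 0 && sd2 <= 0) stop("zero variance in both groups")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @rdname two_sample_t
#' @param x1,x2 raw per-subject vectors
#' @export
two_sample_t_raw <- function(x1, x2) {
  two_sample_t(mean(x1), stats::sd(x1), length(x1),
               mean(x2), stats::sd(x2), length(x2))
}

#' Pearson chi-square for a 2x2 table, without continuity correction
#'
#' The uncorrected statistic n(ad - bc)^2 / (row and column margins); the
#' continuity-corrected form does not reproduce the conventional demographic
#' table values.
#'
#' @param a,b,c,d cell counts (row-wise)
#' @return list: `chisq`, `df` (1), `p`
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("zero margin; chi-square undefined")
  stat <- n * (a * d - b * c)^2 / prod(m)
  list(chisq = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Covariate-adjusted group comparison of one graph measure (ANCOVA)
#'
#' Linear model `metric ~ group + age + gender + mean_fd + verbal_iq +
#' performance_iq + full_iq`; the group coefficient's t test is the
#' covariate-adjusted group effect. Zero-variance or collinear covariates
#' are pruned with a warning (with no usable covariates this reduces
#' exactly to the two-sample t-test). Group is coded 0 = TD, 1 = ADHD so
#' the reported direction is ADHD - TD.
#'
#' @param values per-subject metric values
#' @param group per-subject labels (0/1, logical, or "td"/"adhd")
#' @param covariates data.frame of per-subject covariates (any of age,
#'   gender, mean_fd, verbal_iq, performance_iq, full_iq); may be NULL
#' @param metric label carried into the result
#' @return list of class `stat_result`: `metric`, `statistic` (t), `df`,
#'   `p`, `direction`, `group_means`, `group_sds`, `covariates_used`
#' @export
ancova_group_effect <- function(values, group, covariates = NULL,
                                metric = "metric") {
  g <- if (is.character(group)) as.integer(tolower(group) == "adhd")
       else as.integer(group)
  if (length(unique(g)) != 2) stop("need exactly two groups")
  if (min(table(g)) < 2) stop("need at least 2 subjects per group")
  design <- data.frame(g = g)
  used <- character(0)
  if (!is.null(covariates)) {
    for (cn in colnames(covariates)) {
      v <- covariates[[cn]]
      if (stats::sd(v) > 0) {
        design[[cn]] <- v
        used <- c(used, cn)
      } else {
        warning("covariate '", cn, "' has zero variance; dropped")
      }
    }
  }
  X <- stats::model.matrix(~ ., data = design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!(2 %in% keep)) stop("group column collinear with covariates")
    warning("rank-deficient ANCOVA design; dropping ", ncol(X) - qrX$rank,
            " column(s)")
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  fit <- stats::lm.fit(X, values)
  df <- length(values) - qrX$rank
  if (df < 1) stop("too few subjects for the ANCOVA design")
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(qr.R(qrX))
  j <- which(colnames(X) == "g")
  se <- sqrt(rss / df * XtXinv[j, j])
  tval <- unname(fit$coefficients["g"]) / se
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(metric = metric, statistic = tval, df = df, p = p,
                 direction = sign(unname(fit$coefficients["g"])),
                 group_means = c(td = mean(values[g == 0]),
                                 adhd = mean(values[g == 1])),
                 group_sds = c(td = stats::sd(values[g == 0]),
                               adhd = stats::sd(values[g == 1])),
                 covariates_used = used),
            class = "stat_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, never below the raw p.
#'
#' @param p vector of p-values in [0, 1]
#' @return adjusted p-values in the input order
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Compare a set of graph measures between groups with FDR control
#'
#' Runs [ancova_group_effect()] per metric column and adjusts the p-values
#' jointly by Benjamini-Hochberg.
#'
#' @param metric_matrix subjects x metrics matrix (e.g. AUC-over-sparsity
#'   values)
#' @param group per-subject labels
#' @param covariates data.frame or NULL
#' @return data.frame: metric, t, p, p_fdr, direction, group means/SDs
#' @export
group_compare <- function(metric_matrix, group, covariates = NULL) {
  metric_matrix <- as.matrix(metric_matrix)
  res <- lapply(colnames(metric_matrix), function(m) {
    r <- ancova_group_effect(metric_matrix[, m], group, covariates,
                             metric = m)
    data.frame(metric = m, t = r$statistic, p = r$p,
               direction = r$direction,
               mean_td = r$group_means["td"], sd_td = r$group_sds["td"],
               mean_adhd = r$group_means["adhd"],
               sd_adhd = r$group_sds["adhd"], row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- fdr_bh(out$p)
  out[, c("metric", "t", "p", "p_fdr", "direction",
          "mean_td", "sd_td", "mean_adhd", "sd_adhd")]
}

#' Detect hub nodes from group-averaged nodal centrality
#'
#' Averages the nodal metric over the group's subjects, then flags nodes
#' whose average exceeds the across-node mean by more than two across-node
#' standard deviations.
#'
#' @param nodal_values subjects x nodes matrix of a nodal centrality
#'   (betweenness by default in the pipeline; degree also supported)
#' @param criterion label recorded in the report ("betweenness" or "degree")
#' @param roi_labels optional node labels
#' @return list of class `hub_report`: `criterion`, `threshold`,
#'   `hub_nodes` (indices), `hub_labels`, `node_means`
#' @export
detect_hubs <- function(nodal_values,
                        criterion = c("betweenness", "degree"),
                        roi_labels = NULL) {
  criterion <- match.arg(criterion)
  V <- as.matrix(nodal_values)
  node_means <- colMeans(V)
  m <- mean(node_means)
  s <- stats::sd(node_means)
  if (s == 0) {
    warning("zero across-node SD; no hubs detectable")
    hubs <- integer(0)
    thr <- m
  } else {
    thr <- m + 2 * s
    hubs <- which(node_means > thr)
  }
  structure(list(criterion = criterion, threshold = thr,
                 hub_nodes = hubs,
                 hub_labels = if (!is.null(roi_labels)) roi_labels[hubs],
                 node_means = node_means),
            class = "hub_report")
}
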