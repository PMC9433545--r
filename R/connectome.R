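#' Pearson connectivity matrix from ROI time series
#'
#' @param timeseries T x n matrix (T >= 3); a constant column is an error
#'   naming the offending ROI
#' @return n x n symmetric correlation matrix with unit diagonal; ROI labels
#'   kept as dimnames when the input has column names
#' @export
pearson_connectivity <- function(timeseries) {
  X <- as.matrix(timeseries)
  if (nrow(X) < 3L) stop("need at least 3 time points")
  if (any(!is.finite(X))) stop("non-finite values in time series")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time series for ROI(s): ", paste(bad, collapse = ", "))
  }
  R <- stats::cor(X)
  diag(R) <- 1
  R
}

#' Binarize a correlation matrix at a fixed network density
#'
#' Ranks the n(n-1)/2 upper-triangle values descending (signed value by
#' default: strongest positive correlations first; `absolute = TRUE` ranks
#' |r|) and keeps the top floor(density * n(n-1)/2) pairs as edges. Ties at
#' the cutoff are broken by (row, column) lexicographic order so the result
#' is deterministic.
#'
#' @param R correlation matrix
#' @param density fraction of possible edges to keep, in (0, 1)
#' @param absolute rank by absolute correlation instead of signed
#' @return list of class `binary_network`: `adjacency` (0/1 symmetric,
#'   zero diagonal), `density`, `edge_count`
#' @export
threshold_by_density <- function(R, density, absolute = FALSE) {
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  n <- nrow(R)
  m_max <- n * (n - 1) / 2
  m <- floor(density * m_max)
  if (m < 1) stop("density ", density, " keeps zero edges for n = ", n)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  vals <- R[upper.tri(R)]
  if (absolute) vals <- abs(vals)
  # descending value, ties by (row, col) ascending
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(0, n, n)
  A[cbind(ut[keep, 1], ut[keep, 2])] <- 1
  A <- A + t(A)
  dimnames(A) <- dimnames(R)
  structure(list(adjacency = A, density = density, edge_count = m),
            class = "binary_network")
}

#' Default 10-50% density sweep in 1% steps (41 values)
#' @param from,to,by sweep limits and step
#' @return numeric vector of densities
#' @export
density_sweep <- function(from = 0.10, to = 0.50, by = 0.01) {
  d <- seq(from, to, by = by)
  if (any(diff(d) <= 0) || any(d <= 0) || any(d >= 1)) {
    stop("densities must be strictly increasing fractions in (0, 1)")
  }
  d
}

#' Threshold one connectivity matrix across a density sweep
#'
#' Because every network comes from the same ranking, the sweep is nested:
#' the edge set at a lower density is a subset of the edge set at any higher
#' density.
#'
#' @param R correlation matrix
#' @param sweep densities (default [density_sweep()])
#' @param absolute rank by |r|
#' @return list of `binary_network`, one per density
#' @export
sweep_networks <- function(R, sweep = density_sweep(), absolute = FALSE) {
  lapply(sweep, function(d) threshold_by_density(R, d, absolute = absolute))
}
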