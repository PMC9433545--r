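#' Preprocessing configuration
#'
#' @param discard_initial_volumes volumes dropped for T1 equilibration
#'   (default 10)
#' @param band_low_hz,band_high_hz band-pass edges in Hz (defaults 0.01, 0.1)
#' @param tr_seconds repetition time (default 2)
#' @param fd_scrub_threshold_mm per-volume scrubbing threshold (default 0.5)
#' @param fd_subject_exclusion_mm mean-FD subject exclusion threshold
#'   (default 0.3)
#' @param head_radius_mm radius converting rotations to displacements
#'   (default 50)
#' @param nuisance_mode one of "none", "motion24", "motion24+global"
#' @return object of class `preprocess_config`
#' @export
preprocess_config <- function(discard_initial_volumes = 10L,
                              band_low_hz = 0.01, band_high_hz = 0.1,
                              tr_seconds = 2.0,
                              fd_scrub_threshold_mm = 0.5,
                              fd_subject_exclusion_mm = 0.3,
                              head_radius_mm = 50,
                              nuisance_mode = c("motion24", "none",
                                                "motion24+global")) {
  nuisance_mode <- match.arg(nuisance_mode)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(0 < band_low_hz && band_low_hz < band_high_hz &&
        band_high_hz < nyquist)) {
    stop("need 0 < band_low_hz < band_high_hz < Nyquist = ", nyquist, " Hz")
  }
  if (fd_scrub_threshold_mm <= 0 || fd_subject_exclusion_mm <= 0 ||
      head_radius_mm <= 0) stop("thresholds must be positive")
  structure(list(discard_initial_volumes = as.integer(discard_initial_volumes),
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 tr_seconds = tr_seconds,
                 fd_scrub_threshold_mm = fd_scrub_threshold_mm,
                 fd_subject_exclusion_mm = fd_subject_exclusion_mm,
                 head_radius_mm = head_radius_mm,
                 nuisance_mode = nuisance_mode),
            class = "preprocess_config")
}

#' Frame-wise displacement from a 6-parameter motion trace
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations (rad) converted to arc length
#' on a sphere of radius `head_radius_mm`. FD of the first volume is 0.
#'
#' @param motion T x 6 matrix: translations x/y/z in mm then rotations in rad
#' @param head_radius_mm sphere radius (default 50)
#' @return numeric vector of length T, in mm
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("motion trace must have 6 columns (3 translations, 3 rotations); got ",
         ncol(motion))
  }
  if (nrow(motion) < 2L) stop("need at least 2 volumes")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Subject-level exclusion on mean frame-wise displacement
#'
#' Drop a subject whose mean FD strictly exceeds the threshold ("more than"):
#' at exactly the threshold the subject is kept.
#'
#' @param fd FD series (mm)
#' @param threshold mean-FD exclusion threshold (mm, default 0.3)
#' @return TRUE to keep, FALSE to drop
#' @export
exclude_by_mean_fd <- function(fd, threshold = 0.3) {
  if (length(fd) == 0) stop("empty FD series")
  mean(fd) <= threshold
}

#' Remove per-column linear trends
#'
#' Least-squares line (intercept + slope on volume index) removed from each
#' column; residuals have zero mean by construction.
#'
#' @param timeseries T x p matrix
#' @return detrended matrix of the same shape
#' @export
detrend_linear <- function(timeseries) {
  X <- as.matrix(timeseries)
  if (nrow(X) < 3L) stop("need at least 3 time points")
  t <- seq_len(nrow(X))
  design <- cbind(1, t)
  X - design %*% qr.coef(qr(design), X)
}

#' Ideal (frequency-domain) band-pass filter
#'
#' Zeroes every discrete Fourier coefficient whose frequency lies outside
#' [low, high] Hz, including DC, and inverse-transforms. This rectangular
#' ("ideal") filter is the convention of resting-state toolboxes and is
#' exactly testable: an on-grid sinusoid inside the band passes unchanged, a
#' sinusoid outside is annihilated.
#'
#' @param timeseries T x p matrix
#' @param low_hz,high_hz pass-band edges (Hz)
#' @param tr_seconds sampling interval (s)
#' @return filtered real matrix
#' @export
bandpass <- function(timeseries, low_hz = 0.01, high_hz = 0.1,
                     tr_seconds = 2.0) {
  X <- as.matrix(timeseries)
  T <- nrow(X)
  nyq <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz <= nyq)) {
    stop("need 0 < low < high <= Nyquist = ", nyq, " Hz")
  }
  freqs <- (seq_len(T) - 1) / (T * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)   # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  if (!any(keep)) {
    stop("no Fourier frequencies inside [", low_hz, ", ", high_hz,
         "] Hz at T = ", T, ", TR = ", tr_seconds)
  }
  F <- stats::mvfft(X)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / T
}

#' Censor high-motion volumes and interpolate over them
#'
#' Volumes with FD above `threshold` are marked together with one volume
#' before and two after. Each marked run is replaced, per column, by linear
#' interpolation between its nearest unmarked neighbours; marked runs at the
#' series edges are filled by nearest-value extension.
#'
#' @param timeseries T x p matrix
#' @param fd FD series of length T
#' @param threshold scrub threshold in mm (default 0.5)
#' @return list: `timeseries` (interpolated), `mask` (logical, TRUE =
#'   censored)
#' @export
scrub_interpolate <- function(timeseries, fd, threshold = 0.5) {
  X <- as.matrix(timeseries)
  T <- nrow(X)
  if (length(fd) != T) stop("FD length and time-series rows differ")
  bad <- which(fd > threshold)
  mask <- rep(FALSE, T)
  for (b in bad) mask[max(1, b - 1):min(T, b + 2)] <- TRUE
  if (all(mask)) stop("all volumes censored; subject unusable")
  if (!any(mask)) return(list(timeseries = X, mask = mask))
  good <- which(!mask)
  Xi <- apply(X, 2, function(col) {
    stats::approx(x = good, y = col[good], xout = seq_len(T),
                  method = "linear", rule = 2)$y
  })
  list(timeseries = Xi, mask = mask)
}

friston24 <- function(motion) {
  M <- as.matrix(motion)
  D <- rbind(0, diff(M))       # backward differences; first volume has none
  cbind(M, D, M^2, D^2)
}

#' Regress nuisance signals out of ROI time series
#'
#' Modes: `none` (identity); `motion24`, the Friston 24-parameter expansion
#' (6 parameters, their one-lag backward differences, and the squares of
#' both); `motion24+global`, which adds the grand-mean signal over all ROIs
#' as a global-signal proxy (WM/CSF signals do not exist at ROI level).
#' Residuals of a per-column least-squares fit with intercept are returned;
#' collinear design columns are dropped with a warning.
#'
#' @param timeseries T x p matrix
#' @param motion T x 6 trace (required unless mode = "none")
#' @param mode nuisance model
#' @return residual matrix, orthogonal to the retained design columns
#' @export
nuisance_regress <- function(timeseries, motion = NULL,
                             mode = c("motion24", "none",
                                      "motion24+global")) {
  mode <- match.arg(mode)
  X <- as.matrix(timeseries)
  if (mode == "none") return(X)
  if (is.null(motion)) stop("nuisance mode '", mode, "' needs a motion trace")
  design <- friston24(motion)
  if (mode == "motion24+global") design <- cbind(design, rowMeans(X))
  design <- cbind(1, design)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    warning("nuisance design rank-deficient; dropping ",
            ncol(design) - qrD$rank, " collinear column(s)")
    design <- design[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    qrD <- qr(design)
  }
  X - design %*% qr.coef(qrD, X)
}

#' Run the full time-series cleaning pipeline on one subject
#'
#' Fixed, logged order: discard initial volumes -> linear detrend -> ideal
#' band-pass -> FD scrubbing with interpolation -> nuisance regression. The
#' subject-level mean-FD exclusion decision is returned alongside; the
#' caller decides whether to drop the subject.
#'
#' @param timeseries T x p raw matrix
#' @param motion T x 6 motion trace or NULL
#' @param config a [preprocess_config()]
#' @return list: `timeseries` (cleaned), `qc` (mean_fd, keep,
#'   censored_volumes, n_censored, stages)
#' @export
preprocess_subject <- function(timeseries, motion, config = preprocess_config()) {
  X <- as.matrix(timeseries)
  d <- config$discard_initial_volumes
  if (d >= nrow(X)) stop("cannot discard ", d, " of ", nrow(X), " volumes")
  if (d > 0) {
    X <- X[-seq_len(d), , drop = FALSE]
    if (!is.null(motion)) motion <- motion[-seq_len(d), , drop = FALSE]
  }
  fd <- if (!is.null(motion)) {
    framewise_displacement(motion, config$head_radius_mm)
  } else rep(0, nrow(X))
  keep <- exclude_by_mean_fd(fd, config$fd_subject_exclusion_mm)
  if (!keep) {
    # excluded subjects are not processed further
    return(list(timeseries = NULL,
                qc = list(mean_fd = mean(fd), keep = FALSE,
                          censored_volumes = integer(0), n_censored = 0L,
                          stages = "discard")))
  }
  X <- detrend_linear(X)
  X <- bandpass(X, config$band_low_hz, config$band_high_hz,
                config$tr_seconds)
  sc <- scrub_interpolate(X, fd, config$fd_scrub_threshold_mm)
  X <- nuisance_regress(sc$timeseries, motion, config$nuisance_mode)
  list(timeseries = X,
       qc = list(mean_fd = mean(fd), keep = keep,
                 censored_volumes = which(sc$mask),
                 n_censored = sum(sc$mask),
                 stages = c("discard", "detrend", "bandpass", "scrub",
                            "nuisance")))
}
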