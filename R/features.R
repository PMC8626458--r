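#' Signal magnitude vector
#'
#' Euclidean norm of the three acceleration components at each sample,
#' `sqrt(ax^2 + ay^2 + az^2)`, in g.
#'
#' @param ax,ay,az Acceleration components in g (vectorised), or `ax` may be
#'   an N x 3 matrix with `ay`/`az` missing.
#' @return SMV in g.
#' @export
smv <- function(ax, ay = NULL, az = NULL) {
  if (is.matrix(ax) && is.null(ay)) return(sqrt(rowSums(ax^2)))
  sqrt(ax^2 + ay^2 + az^2)
}

#' Extract the peak-centred observation window
#'
#' Movements are characterised only from the interval of 1 s before and
#' after the highest SMV peak; the rest of the series is ignored. The
#' half-width is `round(sampling_rate)` samples. Ties in the maximum SMV are
#' broken by the earliest index. If the peak lies within 1 s of an edge the
#' window is shifted (not truncated) so the full 2-s span stays inside the
#' trial; trials shorter than 2 s are used whole. Shifting rather than
#' zero-padding avoids distorting the spectral-energy and jerk features.
#'
#' @param trial A trial list (`samples` matrix + `sampling_rate`), e.g. from
#'   [get_trial()] or [generate_trial()].
#' @return List of class `observation_window` with `samples`,
#'   `sampling_rate`, `peak_index` (position of the SMV maximum in the
#'   source trial) and `indices` (source-trial rows covered).
#' @export
extract_window <- function(trial) {
  A <- trial$samples
  n <- nrow(A)
  if (n < 2) stop("extract_window: trial must have at least 2 samples")
  s <- smv(A)
  peak <- which.max(s)  # earliest index on ties
  h <- round(trial$sampling_rate)
  if (n <= 2 * h + 1) {
    idx <- seq_len(n)
  } else {
    start <- peak - h
    start <- max(1L, min(start, n - 2L * h))
    idx <- start:(start + 2L * h)
  }
  structure(list(samples = A[idx, , drop = FALSE],
                 sampling_rate = trial$sampling_rate,
                 peak_index = peak, indices = idx),
            class = "observation_window")
}

FEATURE_NAMES <- c("mean_smv", "std_smv", "mad_smv", "rot_angle",
                   "horiz_mag", "max_pair_diff", "max_smv", "min_smv",
                   "skew_smv", "sma", "dft_energy", "mean_autocorr")

#' The twelve accelerometry features of an observation window
#'
#' All features are computed from the tri-axial samples of the peak-centred
#' window:
#' \describe{
#'   \item{mean_smv}{mean SMV (g): average mobility.}
#'   \item{std_smv}{standard deviation of SMV (g): acceleration
#'     variability.}
#'   \item{mad_smv}{mean absolute difference between consecutive SMV values
#'     (g): sudden fluctuations.}
#'   \item{rot_angle}{mean rotation angle between consecutive acceleration
#'     vectors (radians): change of body orientation. Pairs containing a
#'     zero-norm vector are skipped.}
#'   \item{horiz_mag}{mean magnitude of the two components parallel to the
#'     floor plane (g): loss of verticality. The vertical axis is
#'     auto-detected per window as the axis with the largest mean absolute
#'     value, overridable via `vertical_axis`.}
#'   \item{max_pair_diff}{magnitude of the maximum difference between any
#'     two acceleration vectors in the window (g).}
#'   \item{max_smv}{maximum SMV (g): impact descriptor.}
#'   \item{min_smv}{minimum SMV (g): free-fall valley descriptor.}
#'   \item{skew_smv}{Fisher-Pearson skewness of the SMV series
#'     (dimensionless); 0 for zero-variance windows.}
#'   \item{sma}{signal magnitude area: mean over samples of the per-axis
#'     absolute sum (g).}
#'   \item{dft_energy}{sum over the three axes of the DFT energy
#'     `(1/N) * sum_k |X_k|^2` with the per-axis mean removed first, so the
#'     gravity DC term does not dominate (g^2). By Parseval this equals the
#'     time-domain sum of squared deviations.}
#'   \item{mean_autocorr}{mean of the biased sample autocorrelation of the
#'     SMV series over lags 1..floor(N/2); 0 for zero-variance windows.}
#' }
#'
#' @param win An `observation_window` (or any list with `samples` and
#'   `sampling_rate`).
#' @param vertical_axis Optional axis index (1-3) to treat as vertical for
#'   `horiz_mag`; by default auto-detected.
#' @return Named numeric vector of length 12.
#' @export
feature_vector <- function(win, vertical_axis = NULL) {
  A <- win$samples
  n <- nrow(A)
  if (n < 2) stop("feature_vector: window must have at least 2 samples")
  s <- smv(A)

  f1 <- mean(s)
  f2 <- stats::sd(s)
  f3 <- mean(abs(diff(s)))

  norms <- s
  dots <- rowSums(A[-n, , drop = FALSE] * A[-1, , drop = FALSE])
  denom <- norms[-n] * norms[-1]
  ok <- denom > 0
  f4 <- if (any(ok)) mean(acos(pmin(1, pmax(-1, dots[ok] / denom[ok]))))
        else 0

  v <- if (is.null(vertical_axis)) which.max(abs(colMeans(A)))
       else vertical_axis
  f5 <- mean(sqrt(rowSums(A[, -v, drop = FALSE]^2)))

  f6 <- if (n > 1) max(stats::dist(A)) else 0
  f7 <- max(s)
  f8 <- min(s)

  m2 <- mean((s - f1)^2)
  f9 <- if (m2 > 0) mean((s - f1)^3) / m2^1.5 else 0

  f10 <- mean(rowSums(abs(A)))

  f11 <- sum(apply(A, 2, function(x) {
    x <- x - mean(x)
    sum(Mod(stats::fft(x))^2) / length(x)
  }))

  if (m2 > 0) {
    L <- max(1L, floor(n / 2))
    ac <- stats::acf(s, lag.max = L, plot = FALSE, demean = TRUE)$acf[-1]
    f12 <- mean(ac)
  } else {
    f12 <- 0
  }

  stats::setNames(c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12),
                  FEATURE_NAMES)
}

#' Feature table for a whole dataset
#'
#' Applies [extract_window()] and [feature_vector()] to every trial and
#' returns one row per trial with identifying metadata and the twelve raw
#' (pre-standardisation) features.
#'
#' @param ds An `fds_dataset`.
#' @param feature_fun Plug-in feature extractor `(observation_window) ->`
#'   named numeric vector; defaults to [feature_vector()]. An external
#'   feature table keyed by trial id can be substituted downstream instead.
#' @return Data frame: `trial_id`, `subject_id`, `activity_code`, `klass`,
#'   `category`, then one column per feature.
#' @export
featurize_dataset <- function(ds, feature_fun = feature_vector) {
  feats <- do.call(rbind, lapply(ds$trials$trial_id, function(id) {
    feature_fun(extract_window(get_trial(ds, id)))
  }))
  ai <- match(ds$trials$activity_code, ds$activities$code)
  out <- data.frame(trial_id = ds$trials$trial_id,
                    subject_id = ds$trials$subject_id,
                    activity_code = ds$trials$activity_code,
                    klass = ds$activities$klass[ai],
                    category = ds$activities$category[ai],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Fit z-score standardisation statistics
#'
#' Per-column mean and population standard deviation (divide by N).
#' Zero-variance columns are flagged (and warned about); applying the stats
#' maps them to 0.
#'
#' @param x Numeric matrix (rows = observations).
#' @return List of class `standardization_stats` with `mean`, `sd`,
#'   `zero_var`.
#' @export
fit_standardization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("fit_standardization: empty matrix")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zv <- sdv == 0
  if (any(zv))
    warning(sprintf("zero-variance feature column(s): %s",
                    paste(colnames(x)[zv], collapse = ", ")))
  structure(list(mean = mu, sd = sdv, zero_var = zv),
            class = "standardization_stats")
}

#' Apply z-score standardisation
#'
#' @param x Numeric matrix with the same columns the stats were fitted on.
#' @param stats A `standardization_stats` from [fit_standardization()].
#' @return Standardised matrix; zero-variance columns become all zeros.
#' @export
apply_standardization <- function(x, stats) {
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean))
    stop("apply_standardization: column count mismatch")
  out <- sweep(x, 2, stats$mean)
  sdv <- ifelse(stats$zero_var, 1, stats$sd)
  out <- sweep(out, 2, sdv, "/")
  out[, stats$zero_var] <- 0
  out
}
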