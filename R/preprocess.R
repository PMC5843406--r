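#' Framewise displacement from rigid-body realignment parameters
#'
#' FD at frame `t` is the sum of absolute frame-to-frame differentials of
#' the six rigid-body parameters, with the three rotations (radians)
#' converted to arc length on a sphere of the given radius:
#' `fd(t) = sum |d translations| + radius * sum |d rotations|`. The first
#' frame has no predecessor and gets FD 0 by convention.
#'
#' @param params `T x 6` matrix: three translations (mm), three rotations
#'   (radians).
#' @param radius Head radius in mm used for the rotation-to-arc conversion
#'   (5 mm is a typical rat head, 50 mm a human head).
#' @return Numeric vector of length `T` (mm), `fd[1] = 0`.
#' @export
compute_fd <- function(params, radius = 5) {
  params <- as.matrix(params)
  if (ncol(params) != 6)
    stop("format error: expected 6 rigid-body parameter columns, got ",
         ncol(params))
  if (nrow(params) < 1) stop("format error: empty parameter matrix")
  d <- abs(diff(params))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               radius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Censor high-motion frames and initial volumes
#'
#' Frames with FD above `threshold` are censored together with their
#' immediate temporal neighbors (the frame-to-frame differential implicates
#' both frames of the displaced pair, and the preceding frame is removed as
#' well, mirroring common scrubbing practice). The first `n_initial` frames
#' are discarded to allow magnetization to reach steady state.
#'
#' @param fd Numeric vector of framewise displacement (mm).
#' @param threshold Censoring threshold in mm (default 0.2).
#' @param n_initial Number of leading frames to discard (default 10).
#' @return A `frame_mask`: data.frame with logical `keep` and character
#'   `reason` (`kept`, `fd_censored`, `neighbor_censored`,
#'   `initial_discard`).
#' @export
scrub_frames <- function(fd, threshold = 0.2, n_initial = 10L) {
  if (threshold <= 0) stop("invalid configuration: threshold must be > 0")
  T_len <- length(fd)
  reason <- rep("kept", T_len)
  spike <- which(fd > threshold)
  nb <- unique(c(spike - 1L, spike + 1L))
  nb <- setdiff(nb[nb >= 1L & nb <= T_len], spike)
  reason[nb] <- "neighbor_censored"
  reason[spike] <- "fd_censored"
  if (n_initial > 0L)
    reason[seq_len(min(n_initial, T_len))] <- "initial_discard"
  mask <- data.frame(keep = reason == "kept", reason = reason,
                     stringsAsFactors = FALSE)
  class(mask) <- c("frame_mask", class(mask))
  mask
}

#' Project nuisance regressors out of a time series
#'
#' Ordinary least-squares residualization of every voxel on an intercept
#' plus the supplied regressor columns (e.g. the six motion parameters,
#' white-matter/ventricle signals).
#'
#' @param ts `T x V` time-series matrix.
#' @param regressors `T x R` matrix of nuisance regressors (no intercept
#'   column; one is added internally).
#' @return `T x V` matrix of residuals (zero mean per voxel).
#' @export
nuisance_regress <- function(ts, regressors) {
  ts <- as.matrix(ts); X <- cbind(1, as.matrix(regressors))
  if (nrow(X) != nrow(ts))
    stop("format error: regressors and time series have different lengths")
  if (ncol(X) >= nrow(X))
    stop("degenerate design: more regressors (plus intercept) than frames")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("degenerate design: regressor matrix is rank deficient")
  ts - X %*% qr.coef(qx, ts)
}

#' Zero-phase band-pass filter
#'
#' Retains fluctuations inside `[low, high]` Hz. The default realization is
#' an FFT mask (exact zero-phase, unit pass-band gain, zero stop-band gain,
#' DC removed); `method = "butter"` applies a forward-backward Butterworth
#' filter via the signal package instead. Both honor the same gain
#' contract: pass-band gain in `[0.9, 1]`, stop-band gain (two band-widths
#' away from the edges) below 0.1.
#'
#' @param ts `T x V` time-series matrix.
#' @param low,high Band edges in Hz; require `0 < low < high < 1/(2 tr)`.
#' @param tr Repetition time (sampling interval) in seconds.
#' @param method `"fft"` (default) or `"butter"`.
#' @param order Butterworth order (method `"butter"` only).
#' @return `T x V` filtered matrix.
#' @export
bandpass <- function(ts, low = 0.01, high = 0.1, tr = 1,
                     method = c("fft", "butter"), order = 2L) {
  method <- match.arg(method)
  ts <- as.matrix(ts)
  nyq <- 1 / (2 * tr)
  if (low <= 0 || high <= low || high >= nyq)
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)")
  T_len <- nrow(ts)
  if (method == "fft") {
    freqs <- (seq_len(T_len) - 1) / (T_len * tr)
    freqs <- pmin(freqs, 1 / tr - freqs)         # two-sided spectrum
    keep <- freqs >= low & freqs <= high
    ft <- stats::mvfft(ts)
    ft[!keep, ] <- 0
    Re(stats::mvfft(ft, inverse = TRUE)) / T_len
  } else {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("method 'butter' requires the signal package")
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
    apply(ts, 2, function(x) signal::filtfilt(bf, x))
  }
}
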