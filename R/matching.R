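#' Demean and variance-normalize a time series
#'
#' Per voxel across time: subtract the mean and divide by the standard
#' deviation (population form, denominator `T`, so a two-point voxel
#' `[1, 3]` maps to `[-1, 1]`). The scale choice is immaterial downstream:
#' spatial Pearson correlations are invariant to per-voxel affine maps
#' applied consistently. Zero-variance voxels are set to 0 and flagged.
#'
#' @param ts `T x V` time-series matrix.
#' @return `T x V` normalized matrix with attribute `"flagged"` marking
#'   zero-variance voxels.
#' @export
normalize_frames <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("format error: need at least 2 frames")
  mu <- colMeans(ts)
  out <- sweep(ts, 2, mu)
  sds <- sqrt(colMeans(out^2))
  flagged <- sds == 0
  out[, !flagged] <- sweep(out[, !flagged, drop = FALSE], 2,
                           sds[!flagged], "/")
  out[, flagged] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Match every frame to its best-fitting reference pattern
#'
#' Computes the spatial Pearson correlation between each (normalized) frame
#' and each of the `K` library maps. A frame is labeled with the index of
#' the map with the highest correlation provided that correlation exceeds
#' `min_r`; otherwise (or when the frame is censored) it is labeled 0. Exact
#' argmax ties resolve to the lowest pattern index. The best correlation is
#' recorded for every frame, censored or not.
#'
#' @param ts_norm `T x V` normalized time series (see [normalize_frames()]).
#' @param library A [pattern_library()] on the same voxel grid.
#' @param mask Optional `frame_mask` (or logical keep-vector); censored
#'   frames are labeled 0.
#' @param min_r Minimal spatial correlation for a match (default 0.1, the
#'   value used at K = 40; 0.05 is typical for fine parcellations such as
#'   K = 333).
#' @param bonferroni_n Optional total frame count for a per-frame
#'   Bonferroni gate: frames whose best-match p-value (see
#'   [match_significance()]) exceeds `0.05 / bonferroni_n` are unlabeled.
#'   `NULL` (default) disables the gate.
#' @return An object of class `label_sequence`: data.frame with columns
#'   `label` (in `0..K`) and `best_r`, attributes `K` and `threshold`.
#' @export
match_frames <- function(ts_norm, library, mask = NULL, min_r = 0.1,
                         bonferroni_n = NULL) {
  stopifnot(inherits(library, "pattern_library"))
  ts_norm <- as.matrix(ts_norm)
  if (ncol(ts_norm) != library$V)
    stop("format error: frames and library are on different voxel grids")
  keep <- if (is.null(mask)) rep(TRUE, nrow(ts_norm))
          else if (is.data.frame(mask)) mask$keep else as.logical(mask)
  if (length(keep) != nrow(ts_norm))
    stop("format error: mask length does not match the run length")
  R <- suppressWarnings(stats::cor(t(ts_norm), t(library$maps)))
  R[is.na(R)] <- -Inf                       # constant frames never match
  label <- max.col(R, ties.method = "first")
  best_r <- R[cbind(seq_len(nrow(R)), label)]
  label[!is.finite(best_r) | best_r <= min_r] <- 0L
  if (!is.null(bonferroni_n)) {
    p <- vapply(best_r, function(r)
      if (is.finite(r)) match_significance(r, library$V) else 1, numeric(1))
    label[p >= 0.05 / bonferroni_n] <- 0L
  }
  label[!keep] <- 0L
  best_r[!is.finite(best_r)] <- NA_real_
  out <- data.frame(label = as.integer(label), best_r = best_r)
  class(out) <- c("label_sequence", class(out))
  attr(out, "K") <- library$K
  attr(out, "threshold") <- min_r
  out
}

# Integer labels from a label_sequence or plain vector.
label_vector <- function(seq) {
  if (is.data.frame(seq)) as.integer(seq$label) else as.integer(seq)
}

#' Significance of a spatial correlation
#'
#' Two-tailed p-value of a Pearson correlation `r` over `V` spatial points
#' under the t distribution with `V - 2` degrees of freedom. With the
#' thresholds used in frame matching this p is vanishingly small (r = 0.1
#' at V = 6000 gives p below 1e-13), which is why the correlation
#' threshold, not the p-value, is the operative gate.
#'
#' @param r Correlation coefficient.
#' @param V Number of spatial points (>= 3).
#' @return Two-tailed p-value; 0 when `|r| >= 1`.
#' @export
match_significance <- function(r, V) {
  if (V < 3) stop("format error: V must be >= 3")
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt(V - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = V - 2)
}
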