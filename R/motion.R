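#' Split subjects into low- and high-motion subgroups
#'
#' Partitions subjects at the median of their mean framewise displacement:
#' the half with the lowest mean FD forms subgroup `low`, the rest
#' subgroup `high`. With an odd number of subjects the extra subject goes
#' to `high` (strictly-below-median reading). Ties at the median are
#' broken by subject order, deterministically, with a warning.
#'
#' @param subject_fd_means Numeric vector of per-subject mean FD (mm).
#' @return Factor of length `n` with levels `low`, `high`.
#' @export
motion_split <- function(subject_fd_means) {
  n <- length(subject_fd_means)
  if (n < 2) stop("need at least 2 subjects")
  ord <- order(subject_fd_means, seq_len(n))
  n_low <- floor(n / 2)
  grp <- rep("high", n)
  grp[ord[seq_len(n_low)]] <- "low"
  cut_lo <- subject_fd_means[ord[n_low]]
  cut_hi <- subject_fd_means[ord[n_low + 1L]]
  if (cut_lo == cut_hi)
    warning("tied mean FD at the median; split resolved by subject order")
  factor(grp, levels = c("low", "high"))
}

#' Compare motion of in-transition versus steady frames
#'
#' A kept, matched frame is "in transition" when its preceding and/or
#' successive frame carries a different (nonzero) pattern label; frames
#' whose neighbors all carry the same label are "steady". The two FD
#' samples are compared with a two-sample t-test (equal variances). If
#' transitions tracked head motion, in-transition frames would show
#' elevated FD.
#'
#' @param seqs List of `label_sequence` objects (or label vectors), one
#'   per run.
#' @param fd List of FD vectors aligned with `seqs`.
#' @return List with `fd_transition`, `fd_steady` (the two FD samples),
#'   `t` (statistic), `p` (two-tailed), `in_transition` (list of logical
#'   vectors marking classified in-transition frames).
#' @export
transition_frame_fd <- function(seqs, fd) {
  if (length(seqs) != length(fd))
    stop("format error: one FD trace per run is required")
  fd_tr <- numeric(0); fd_st <- numeric(0)
  marks <- vector("list", length(seqs))
  for (r in seq_along(seqs)) {
    labs <- label_vector(seqs[[r]])
    f <- fd[[r]]
    if (length(labs) != length(f))
      stop("format error: FD and label sequence lengths differ")
    T_len <- length(labs)
    prev <- c(NA_integer_, labs[-T_len])
    nxt <- c(labs[-1], NA_integer_)
    diff_prev <- !is.na(prev) & prev != 0L & prev != labs
    diff_next <- !is.na(nxt) & nxt != 0L & nxt != labs
    in_tr <- labs != 0L & (diff_prev | diff_next)
    steady <- labs != 0L & !in_tr
    fd_tr <- c(fd_tr, f[in_tr])
    fd_st <- c(fd_st, f[steady])
    marks[[r]] <- in_tr
  }
  if (length(fd_tr) < 2 || length(fd_st) < 2) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- stats::t.test(fd_tr, fd_st, var.equal = TRUE)
  }
  list(fd_transition = fd_tr, fd_steady = fd_st,
       t = unname(tt$statistic), p = tt$p.value, in_transition = marks)
}

#' Mean motion per transition type
#'
#' For every counted transition `i -> j` (adjacent frames with distinct
#' nonzero labels), the FD of the two frames of the pair is averaged;
#' entry `(i, j)` of the result is the mean over all occurrences of that
#' transition. The off-diagonal correlation between this FD matrix and the
#' raw transition-count matrix says whether frequently occurring
#' transitions are the high-motion ones (near zero when transitions are
#' motion-independent).
#'
#' @param seqs List of `label_sequence` objects (or label vectors).
#' @param fd List of FD vectors aligned with `seqs`.
#' @param K Number of patterns.
#' @return List with `fd_matrix` (`K x K`, `NA` where a transition never
#'   occurs), `counts` (the raw transition count matrix), `correlation`
#'   (Pearson, off-diagonal cells with observed transitions only).
#' @export
transition_fd_matrix <- function(seqs, fd, K = attr(seqs[[1]], "K")) {
  if (length(seqs) != length(fd))
    stop("format error: one FD trace per run is required")
  if (is.null(K)) stop("K must be supplied for plain label vectors")
  fd_sum <- matrix(0, K, K)
  n_tr <- matrix(0, K, K)
  for (r in seq_along(seqs)) {
    labs <- label_vector(seqs[[r]])
    f <- fd[[r]]
    T_len <- length(labs)
    if (T_len < 2) next
    from <- labs[-T_len]; to <- labs[-1]
    ok <- which(from != 0L & to != 0L & from != to)
    for (t in ok) {
      i <- from[t]; j <- to[t]
      fd_sum[i, j] <- fd_sum[i, j] + (f[t] + f[t + 1L]) / 2
      n_tr[i, j] <- n_tr[i, j] + 1
    }
  }
  fd_m <- ifelse(n_tr > 0, fd_sum / n_tr, NA_real_)
  od <- row(fd_m) != col(fd_m) & n_tr > 0
  correlation <- if (sum(od) >= 3 && stats::sd(fd_m[od]) > 0 &&
                       stats::sd(n_tr[od]) > 0)
    stats::cor(fd_m[od], n_tr[od]) else NA_real_
  list(fd_matrix = fd_m, counts = n_tr, correlation = correlation)
}

#' Motion-split reproducibility versus random splits
#'
#' Computes the split-half reproducibility for the motion-based split and
#' for `n_random` random balanced splits, returning the two-sided
#' empirical p-value of the motion split within the random-split
#' distribution. A small p would indicate that motion level shapes the
#' transition structure.
#'
#' @param per_subject List of subject-level `transition_matrix` objects.
#' @param subject_fd_means Per-subject mean FD (mm).
#' @param n_random Number of random splits (default 1000).
#' @param seed Integer seed.
#' @param regress,sim Passed to [split_half_reproducibility()].
#' @return List with `r_motion`, `r_random` (vector), `p` (two-sided
#'   empirical).
#' @export
motion_split_test <- function(per_subject, subject_fd_means,
                              n_random = 1000L, seed = 1L,
                              regress = FALSE, sim = NULL) {
  n <- length(per_subject)
  stopifnot(length(subject_fd_means) == n)
  grp <- motion_split(subject_fd_means)
  r_motion <- as.numeric(split_half_reproducibility(per_subject, grp,
                                                    regress = regress,
                                                    sim = sim))
  n_low <- sum(grp == "low")
  rs <- local_rng(seed)
  r_random <- vapply(seq_len(n_random), function(b) {
    idx <- rs$sample(n, n_low)
    g <- factor(ifelse(seq_len(n) %in% idx, "A", "B"))
    as.numeric(split_half_reproducibility(per_subject, g,
                                          regress = regress, sim = sim))
  }, numeric(1))
  p_lo <- (1 + sum(r_random <= r_motion)) / (n_random + 1)
  p_hi <- (1 + sum(r_random >= r_motion)) / (n_random + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(r_motion = r_motion, r_random = r_random, p = p)
}
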