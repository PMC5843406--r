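#' Transition matrix constructor
#'
#' A `K x K` matrix of directed pattern-to-pattern transitions with a
#' `level` attribute tracking its processing stage (`raw_counts`,
#' `normalized`, `residualized`, `thresholded`) and a free-form
#' `provenance` attribute.
#'
#' @param values `K x K` numeric matrix (diagonal unused, kept at 0).
#' @param level Processing stage.
#' @param provenance Character note on what was aggregated.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(values,
                              level = c("raw_counts", "normalized",
                                        "residualized", "thresholded"),
                              provenance = "") {
  level <- match.arg(level)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (any(values[!is.na(values)] < 0) && level != "residualized")
    stop("transition matrices are nonnegative")
  structure(values, class = c("transition_matrix", "matrix"),
            level = level, provenance = provenance)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix (K=%d, level=%s%s)\n", nrow(x),
              attr(x, "level"),
              if (nzchar(attr(x, "provenance")))
                paste0(", ", attr(x, "provenance")) else ""))
  print(unclass(x), ...)
  invisible(x)
}

off_diag <- function(m) m[row(m) != col(m)]

`off_diag<-` <- function(m, value) {
  m[row(m) != col(m)] <- value
  m
}

#' Count directed transitions in a label sequence
#'
#' Entry `(i, j)` counts adjacent frame pairs labeled `(i, j)` with
#' `i != j` and both nonzero. Pairs with identical labels (dwell) or
#' involving the 0 label (censored/unmatched frames) contribute nothing, so
#' a 0 frame acts as a separator rather than a bridge.
#'
#' @param seq A `label_sequence` or integer vector with values in `0..K`.
#' @param K Number of patterns (taken from the `label_sequence` attribute
#'   when available).
#' @return A `transition_matrix` of level `raw_counts`.
#' @export
count_transitions <- function(seq, K = attr(seq, "K")) {
  labs <- label_vector(seq)
  if (is.null(K)) stop("K must be supplied for plain label vectors")
  if (any(labs < 0 | labs > K))
    stop("label error: labels must lie in 0..K")
  m <- count_transitions_core(labs, K)
  transition_matrix(m, level = "raw_counts", provenance = "1 run")
}

# Bare counting kernel used in the permutation inner loop.
count_transitions_core <- function(labs, K) {
  T_len <- length(labs)
  m <- matrix(0, K, K)
  if (T_len < 2) return(m)
  from <- labs[-T_len]; to <- labs[-1]
  ok <- from != 0L & to != 0L & from != to
  if (any(ok)) {
    idx <- (to[ok] - 1L) * K + from[ok]
    tab <- tabulate(idx, nbins = K * K)
    m[] <- tab
  }
  m
}

#' Aggregate transition matrices
#'
#' Entrywise sum or mean across runs or subjects.
#'
#' @param matrices Nonempty list of `transition_matrix` objects of the
#'   same size.
#' @param mode `"sum"` or `"mean"`.
#' @return A `transition_matrix` with updated provenance; level follows the
#'   inputs (raw counts stay raw for sums; means are still reported as
#'   `raw_counts` scale until normalization).
#' @export
aggregate_transitions <- function(matrices, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(matrices) == 0) stop("empty input: nothing to aggregate")
  Ks <- vapply(matrices, nrow, integer(1))
  if (length(unique(Ks)) != 1)
    stop("shape error: matrices of mixed size cannot be aggregated")
  total <- Reduce(`+`, lapply(matrices, unclass))
  if (mode == "mean") total <- total / length(matrices)
  transition_matrix(total, level = "raw_counts",
                    provenance = sprintf("%s of %d matrices", mode,
                                         length(matrices)))
}

#' Min-max rescale the off-diagonal entries to [0, 1]
#'
#' The diagonal is left at 0 and excluded from the scaling. Pearson
#' correlations between matrices are invariant to this affine map, so
#' reproducibility measures do not depend on the scaling constants.
#'
#' @param m A `transition_matrix`.
#' @return A `transition_matrix` of level `normalized`.
#' @export
normalize01 <- function(m) {
  od <- off_diag(m)
  if (all(od == 0)) stop("degenerate input: all-zero transition matrix")
  rng <- range(od)
  if (rng[1] == rng[2]) {
    warning("constant off-diagonal entries; normalized matrix is all zero")
    scaled <- rep(0, length(od))
  } else {
    scaled <- (od - rng[1]) / (rng[2] - rng[1])
  }
  out <- unclass(m)
  out[row(out) != col(out)] <- scaled
  diag(out) <- 0
  transition_matrix(out, level = "normalized",
                    provenance = attr(m, "provenance"))
}

#' Regress pattern similarity out of a transition matrix
#'
#' Transitions between spatially similar patterns could be over-counted
#' simply because similar maps compete for the same frames. This removes
#' the linear dependence: each ordered off-diagonal cell `(i, j)` is one
#' observation, regressed on the symmetric similarity `sim[i, j]`; the
#' residuals (intercept removed as well) replace the off-diagonal entries.
#'
#' @param m A `transition_matrix`.
#' @param sim `K x K` spatial-similarity matrix.
#' @param cells Optional logical `K x K` matrix restricting the regression
#'   to a subset of off-diagonal cells (used after thresholding); other
#'   cells are left untouched.
#' @return A `transition_matrix` of level `residualized`.
#' @export
regress_similarity <- function(m, sim, cells = NULL) {
  K <- nrow(m)
  if (nrow(sim) != K || ncol(sim) != K)
    stop("shape error: similarity matrix size does not match")
  use <- row(m) != col(m)
  if (!is.null(cells)) use <- use & cells
  y <- m[use]; x <- sim[use]
  if (length(unique(x)) < 2)
    stop("degenerate regressor: similarity has no variance over the cells used")
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- unclass(m)
  out[use] <- fit$residuals
  transition_matrix(out, level = "residualized",
                    provenance = attr(m, "provenance"))
}

#' Split-half reproducibility of the transition structure
#'
#' Builds each subgroup's group-level matrix (aggregate across subjects,
#' min-max normalize, optionally regress out pattern similarity) and
#' returns the Pearson correlation of the corresponding off-diagonal
#' entries.
#'
#' @param per_subject List of subject-level `transition_matrix` objects.
#' @param groups Vector (coercible to factor with 2 levels) assigning each
#'   subject to a subgroup.
#' @param regress Regress pattern similarity out of both matrices first?
#' @param sim `K x K` similarity matrix (required when `regress = TRUE`).
#' @param mode Aggregation across subjects within a subgroup (default
#'   `"mean"`, mirroring group-level averaging of subject matrices).
#' @return Correlation coefficient (length-1 numeric) with attribute
#'   `"matrices"` holding the two subgroup matrices.
#' @export
split_half_reproducibility <- function(per_subject, groups, regress = FALSE,
                                       sim = NULL, mode = "mean") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("both subgroups must be nonempty")
  if (regress && is.null(sim))
    stop("similarity matrix required when regress = TRUE")
  build <- function(idx) {
    g <- normalize01(aggregate_transitions(per_subject[idx], mode = mode))
    if (regress) g <- regress_similarity(g, sim)
    g
  }
  g1 <- build(which(groups == levels(groups)[1]))
  g2 <- build(which(groups == levels(groups)[2]))
  r <- stats::cor(off_diag(g1), off_diag(g2))
  attr(r, "matrices") <- list(g1, g2)
  r
}

#' Individual-level reproducibility against the group matrix
#'
#' Pearson correlation of off-diagonal entries between each subject's
#' matrix and the group matrix; the mean is taken on the Fisher-z scale and
#' back-transformed, the SD is of the raw correlations.
#'
#' @param per_subject List of subject-level `transition_matrix` objects.
#' @param group Group-level `transition_matrix`.
#' @return List with `mean`, `sd`, and the per-subject `r` vector.
#' @export
individual_reproducibility <- function(per_subject, group) {
  if (length(per_subject) == 0) stop("empty input: need at least 1 subject")
  g_od <- off_diag(group)
  r <- vapply(per_subject, function(m) stats::cor(off_diag(m), g_od),
              numeric(1))
  r_clip <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  list(mean = tanh(mean(atanh(r_clip))), sd = stats::sd(r),
       r = r)
}

#' Subject-level transition matrices from label sequences
#'
#' Sums the run-level transition counts within each subject (runs never
#' bridge transitions: counting is per run, then summed).
#'
#' @param seqs List of `label_sequence` objects (or plain label vectors).
#' @param subject_of_run Subject id per run.
#' @param K Number of patterns.
#' @return Named list of subject-level `transition_matrix` objects.
#' @export
subject_matrices <- function(seqs, subject_of_run, K = attr(seqs[[1]], "K")) {
  subject_of_run <- as.factor(subject_of_run)
  per_run <- lapply(seqs, count_transitions, K = K)
  lapply(split(per_run, subject_of_run), aggregate_transitions,
         mode = "sum")
}
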