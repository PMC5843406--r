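#' Collapse consecutive repeats of a label
#'
#' Maximal runs of the same token become a single token (`x x x x` becomes
#' `x`), including runs of 0. Dwell time is thereby removed, so a
#' permutation of the consolidated sequence randomizes transition order
#' only, which is the null of interest.
#'
#' @param seq A `label_sequence` or integer vector.
#' @return Integer vector of consolidated tokens.
#' @export
consolidate <- function(seq) {
  labs <- label_vector(seq)
  if (length(labs) == 0) return(integer(0))
  labs[c(TRUE, labs[-1] != labs[-length(labs)])]
}

#' Permutation test on consolidated label sequences
#'
#' The observed statistic for each ordered pair `(i, j)` is its share of
#' all counted transitions, aggregated over runs. Each permutation
#' uniformly shuffles the consolidated tokens *within each run* (0 tokens
#' shuffled along with the rest), re-counts transitions with the standard
#' rules, and aggregates. P-values use the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' Comparing transition *shares* rather than raw counts makes observed and
#' permuted sequences commensurable: a consolidated sequence has no
#' adjacent repeats, while its shuffles do, so shuffles always carry fewer
#' countable adjacencies. Raw-count comparison would therefore inflate
#' every entry; the share statistic asks the intended question -- whether
#' transition `(i, j)` is over-represented among the transitions that
#' occur -- and keeps the test calibrated under an order-free null.
#'
#' @param seqs A single sequence or a list of sequences (`label_sequence`
#'   objects or integer vectors); consolidation is applied internally, so
#'   raw sequences may be passed.
#' @param K Number of patterns.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param keep_null Retain the full null sample array
#'   (`n_perm x K x K`)? Off by default; exceedance counts suffice for p.
#' @return An object of class `permutation_result`: list with `p` (`K x K`,
#'   diagonal NA), `observed` (`transition_matrix`), `n_perm`, `seed`, and
#'   optionally `null_counts`.
#' @export
permutation_test <- function(seqs, K = NULL, n_perm = 10000L, seed = 1L,
                             keep_null = FALSE) {
  if (!is.list(seqs) || is.data.frame(seqs)) seqs <- list(seqs)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(K)) K <- attr(seqs[[1]], "K")
  if (is.null(K)) stop("K must be supplied for plain label vectors")
  tokens <- lapply(seqs, consolidate)
  obs <- Reduce(`+`, lapply(tokens, count_transitions_core, K = K))
  obs_stat <- transition_share(obs)
  rs <- local_rng(seed)
  ge <- matrix(0, K, K)
  null_arr <- if (keep_null) array(NA_real_, c(n_perm, K, K)) else NULL
  lens <- lengths(tokens)
  for (b in seq_len(n_perm)) {
    null_m <- matrix(0, K, K)
    for (r in seq_along(tokens)) {
      perm <- tokens[[r]][rs$sample(lens[r], lens[r])]
      null_m <- null_m + count_transitions_core(perm, K)
    }
    ge <- ge + (transition_share(null_m) >= obs_stat - 1e-12)
    if (keep_null) null_arr[b, , ] <- null_m
  }
  p <- (1 + ge) / (n_perm + 1)
  diag(p) <- NA_real_
  out <- list(p = p,
              observed = transition_matrix(obs, level = "raw_counts",
                                           provenance = sprintf(
                                             "consolidated, %d run(s)",
                                             length(tokens))),
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              null_counts = null_arr)
  class(out) <- "permutation_result"
  out
}

# Per-cell share of all counted transitions (all zeros when none occur).
transition_share <- function(m) {
  tot <- sum(m)
  if (tot == 0) m else m / tot
}

#' @export
print.permutation_result <- function(x, ...) {
  sig <- sum(x$p < 0.05, na.rm = TRUE)
  cat(sprintf("permutation_result: K=%d, n_perm=%d, %d/%d entries with p < 0.05 (uncorrected)\n",
              nrow(x$p), x$n_perm, sig, sum(!is.na(x$p))))
  invisible(x)
}

#' Threshold a group transition matrix by permutation FDR
#'
#' Benjamini-Hochberg correction over the `K (K - 1)` off-diagonal
#' permutation p-values at rate `q`; non-surviving entries are zeroed,
#' survivors are min-max rescaled to `[0, 1]`, pattern similarity is
#' regressed out of the surviving cells, and negative residuals are floored
#' at a small positive epsilon so every surviving cell carries a positive
#' edge weight.
#'
#' @param group Group-level `transition_matrix`.
#' @param perm A `permutation_result` for the same `K`.
#' @param q FDR rate (in `(0, 1)`, default 0.05).
#' @param sim Optional `K x K` similarity matrix; `NULL` skips the
#'   similarity regression.
#' @param epsilon Floor for non-positive residual weights (default 1e-6).
#' @return A `transition_matrix` of level `thresholded` with attribute
#'   `"survivors"` (logical `K x K`); all-zero with a warning when nothing
#'   survives.
#' @export
threshold_matrix <- function(group, perm, q = 0.05, sim = NULL,
                             epsilon = 1e-6) {
  if (q <= 0 || q >= 1) stop("invalid configuration: q must be in (0, 1)")
  K <- nrow(group)
  stopifnot(nrow(perm$p) == K)
  od <- row(group) != col(group)
  p_adj <- matrix(NA_real_, K, K)
  p_adj[od] <- stats::p.adjust(perm$p[od], method = "BH")
  surv <- !is.na(p_adj) & p_adj <= q
  out <- matrix(0, K, K)
  if (!any(surv)) {
    warning("no transition survives FDR thresholding; empty graph")
    res <- transition_matrix(out, level = "thresholded",
                             provenance = attr(group, "provenance"))
    attr(res, "survivors") <- surv
    return(res)
  }
  vals <- unclass(group)[surv]
  rng <- range(vals)
  out[surv] <- if (rng[1] == rng[2]) 1 else (vals - rng[1]) / diff(rng)
  m <- transition_matrix(out, level = "residualized",
                         provenance = attr(group, "provenance"))
  if (!is.null(sim) && sum(surv) >= 3) {
    m <- tryCatch(regress_similarity(m, sim, cells = surv),
                  error = function(e) m)
  }
  final <- unclass(m)
  final[surv] <- pmax(final[surv], epsilon)
  final[!surv] <- 0
  res <- transition_matrix(final, level = "thresholded",
                           provenance = attr(group, "provenance"))
  attr(res, "survivors") <- surv
  attr(res, "p_adjusted") <- p_adj
  res
}
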