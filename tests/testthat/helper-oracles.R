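# Independent oracles used across the suite. These are deliberately naive
# implementations (brute force, exhaustive enumeration) kept separate from
# the package's own algorithms.

# All-pairs shortest-path distances by Floyd-Warshall on edge lengths
# 1/weight.
fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1 / adj[adj > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Betweenness centrality from shortest-path counts accumulated alongside
# Floyd-Warshall (pair-dependency formulation).
fw_betweenness <- function(adj, tol = 1e-12) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  N <- matrix(0, n, n)
  D[adj > 0] <- 1 / adj[adj > 0]
  N[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == k || j == k) next
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j] - tol) {
      D[i, j] <- alt
      N[i, j] <- N[i, k] * N[k, j]
    } else if (abs(alt - D[i, j]) <= tol && is.finite(alt)) {
      N[i, j] <- N[i, j] + N[i, k] * N[k, j]
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    if (!is.finite(D[s, t]) || N[s, t] == 0) next
    if (abs(D[s, v] + D[v, t] - D[s, t]) <= tol)
      btw[v] <- btw[v] + N[s, v] * N[v, t] / N[s, t]
  }
  btw
}

# All permutations of 1..n as an (n! x n) matrix (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    ins <- matrix(0L, nrow(sub), n)
    ins[, pos] <- n
    ins[, -pos] <- sub
    ins
  }))
}

# Naive transition counter used as the oracle against count_transitions.
naive_counts <- function(labs, K) {
  m <- matrix(0, K, K)
  for (t in seq_len(length(labs) - 1)) {
    i <- labs[t]; j <- labs[t + 1]
    if (i != 0 && j != 0 && i != j) m[i, j] <- m[i, j] + 1
  }
  m
}

# Exact permutation p-values for a short token sequence: exhaustive
# enumeration over all arrangements, on the transition-share statistic
# (each cell's fraction of all counted transitions).
exhaustive_perm_p <- function(tokens, K) {
  share <- function(m) if (sum(m) == 0) m else m / sum(m)
  obs <- share(naive_counts(tokens, K))
  P <- all_perms(length(tokens))
  ge <- matrix(0, K, K)
  for (b in seq_len(nrow(P))) {
    ge <- ge + (share(naive_counts(tokens[P[b, ]], K)) >= obs - 1e-12)
  }
  ge / nrow(P)
}

# Small deterministic cohort of label-chain subjects sharing one planted
# transition structure.
make_cohort <- function(n_subjects, T_len, P, seed, runs_per_subject = 1L) {
  K <- nrow(P)
  lapply(seq_len(n_subjects), function(s) {
    runs <- lapply(seq_len(runs_per_subject), function(r)
      generate_label_chain(P, T_len, seed = seed + 1000L * s + r))
    mats <- lapply(runs, count_transitions, K = K)
    aggregate_transitions(mats, mode = "sum")
  })
}
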