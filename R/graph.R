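#' Build the directed weighted transition graph
#'
#' Every positive off-diagonal entry of a thresholded transition matrix
#' becomes a directed edge with the entry as its weight.
#'
#' @param m A `transition_matrix` (typically level `thresholded`).
#' @return An igraph directed weighted graph with `K` vertices; the
#'   adjacency matrix is stored in the graph attribute `"adjacency"`.
#' @export
build_graph <- function(m) {
  K <- nrow(m)
  adj <- unclass(m)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "adjacency", adj)
  g
}

#' Connection density of a directed graph
#'
#' Fraction of the `K (K - 1)` possible directed edges that are present.
#'
#' @param g An igraph directed graph.
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(g) {
  K <- igraph::vcount(g)
  if (K < 2) stop("density needs at least 2 nodes")
  igraph::ecount(g) / (K * (K - 1))
}

#' Node-level graph metrics
#'
#' Computes, per node: strength (in-strength plus out-strength), weighted
#' betweenness centrality, characteristic path length (mean finite directed
#' shortest-path distance to the other nodes), and the directed weighted
#' local clustering coefficient (cube-root-of-weights triangle
#' formulation). Shortest paths use edge lengths `1 / weight`, so heavier
#' edges are shorter. Nodes that cannot reach any other node get `NA` path
#' length and are flagged.
#'
#' @param g An igraph directed weighted graph (from [build_graph()]).
#' @return A `data.frame` (one row per node) with columns `node`,
#'   `strength`, `betweenness`, `cpl`, `clustering`, `unreachable`.
#' @export
node_metrics <- function(g) {
  if (igraph::ecount(g) < 1) stop("graph has no edges")
  K <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  len <- 1 / w
  strength <- igraph::strength(g, mode = "all")
  btw <- igraph::betweenness(g, directed = TRUE, weights = len)
  D <- igraph::distances(g, mode = "out", weights = len)
  diag(D) <- NA
  cpl <- apply(D, 1, function(d) {
    fin <- d[is.finite(d) & !is.na(d)]
    if (length(fin) == 0) NA_real_ else mean(fin)
  })
  unreachable <- apply(D, 1, function(d) any(is.infinite(d)))
  adj <- igraph::graph_attr(g, "adjacency")
  clust <- clustering_dir_weighted(adj)
  data.frame(node = seq_len(K), strength = as.numeric(strength),
             betweenness = as.numeric(btw), cpl = cpl,
             clustering = clust, unreachable = unreachable)
}

# Directed weighted clustering coefficient (cube-root-of-weights triangle
# formulation over all directed triangle motifs; weights scaled by the
# maximum so the coefficient lies in [0, 1]).
clustering_dir_weighted <- function(adj) {
  K <- nrow(adj)
  A <- (adj > 0) * 1
  mx <- max(adj)
  if (mx == 0) return(rep(0, K))
  W3 <- (adj / mx)^(1 / 3)
  S <- W3 + t(W3)
  t_i <- diag(S %*% S %*% S) / 2
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- diag(A %*% A)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  out <- ifelse(denom > 0, t_i / denom, 0)
  as.numeric(out)
}

#' Hub scores from node metrics
#'
#' One point per criterion met: (1) upper `pct` percentile in strength,
#' (2) upper `pct` percentile in betweenness, (3) lower `pct` percentile in
#' characteristic path length, (4) lower `pct` percentile in clustering.
#' Percentile cutoffs use linear interpolation (quantile type 7) and ties
#' at a cutoff count as meeting the criterion. Nodes scoring at least 3
#' are flagged as hubs.
#'
#' @param report Output of [node_metrics()].
#' @param pct Percentile in `(0, 50)` (default 20).
#' @return The `report` with added columns `hub_score` (0-4) and `is_hub`.
#' @export
hub_scores <- function(report, pct = 20) {
  if (pct <= 0 || pct >= 50) stop("pct must be in (0, 50)")
  p <- pct / 100
  hi <- function(x) x >= stats::quantile(x, 1 - p, na.rm = TRUE, names = FALSE)
  lo <- function(x) x <= stats::quantile(x, p, na.rm = TRUE, names = FALSE)
  score <- hi(report$strength) + hi(report$betweenness) +
    lo(report$cpl) + lo(report$clustering)
  score[is.na(score)] <- 0L
  report$hub_score <- as.integer(score)
  report$is_hub <- report$hub_score >= 3L
  report
}

#' Louvain community detection for directed weighted graphs
#'
#' Greedy modularity optimization with the directed null model
#' `Q = (1/m) * sum_ij [A_ij - k_i^out k_j^in / m] delta(c_i, c_j)` at
#' resolution 1: repeated local node moves in random order followed by
#' community aggregation, until no move improves Q.
#'
#' @param adj `K x K` nonnegative adjacency matrix (weights).
#' @param seed Integer seed controlling the node visiting order.
#' @return Integer membership vector of length `K` (communities numbered
#'   from 1).
#' @export
louvain_directed <- function(adj, seed = 1L) {
  adj <- as.matrix(adj)
  diag(adj) <- 0
  m_tot <- sum(adj)
  if (m_tot == 0) return(seq_len(nrow(adj)))
  rs <- local_rng(seed)
  W <- adj
  membership <- seq_len(nrow(adj))   # node -> community at original scale
  repeat {
    n <- nrow(W)
    comm <- seq_len(n)
    k_out <- rowSums(W); k_in <- colSums(W)
    sig_out <- k_out; sig_in <- k_in     # per-community totals
    improved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in rs$sample(n, n)) {
        ci <- comm[i]
        # weights from/to i into each community, excluding i's self-loop
        # (a self-loop contributes to Q identically in every placement)
        xo <- W[i, ]; xo[i] <- 0
        xi <- W[, i]; xi[i] <- 0
        w_to <- tapply_sum(xo, comm, n)
        w_from <- tapply_sum(xi, comm, n)
        sig_out[ci] <- sig_out[ci] - k_out[i]
        sig_in[ci] <- sig_in[ci] - k_in[i]
        cand <- unique(c(ci, comm[xo > 0], comm[xi > 0]))
        gain <- (w_to[cand] + w_from[cand]) / m_tot -
          (k_out[i] * sig_in[cand] + k_in[i] * sig_out[cand]) / m_tot^2
        best <- cand[which.max(gain)]
        if (gain[match(best, cand)] > gain[match(ci, cand)] + 1e-12) {
          comm[i] <- best
          moved <- TRUE
          improved_any <- TRUE
        }
        sig_out[comm[i]] <- sig_out[comm[i]] + k_out[i]
        sig_in[comm[i]] <- sig_in[comm[i]] + k_in[i]
      }
      if (!moved) break
    }
    comm <- match(comm, unique(comm))
    membership <- comm[membership]
    if (!improved_any || max(comm) == n) break
    # aggregate communities into super-nodes
    n2 <- max(comm)
    W2 <- matrix(0, n2, n2)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (W[a, b] != 0)
        W2[comm[a], comm[b]] <- W2[comm[a], comm[b]] + W[a, b]
    }
    W <- W2
  }
  match(membership, unique(membership))
}

# Sum x by group labels in 1..n, returning a length-n vector.
tapply_sum <- function(x, groups, n) {
  out <- numeric(n)
  pos <- which(x != 0)
  for (j in pos) out[groups[j]] <- out[groups[j]] + x[j]
  out
}

#' Consensus community structure by repeated Louvain
#'
#' Runs [louvain_directed()] `n_rep` times with different random node
#' orders, averages the node co-assignment matrices, binarizes the average
#' at `tau`, and reads the final communities off the connected components
#' of the binarized matrix.
#'
#' @param g An igraph graph from [build_graph()], or an adjacency matrix.
#' @param n_rep Number of repetitions (default 1000).
#' @param tau Binarization threshold in `(0, 1]` (default 0.9).
#' @param seed Integer seed.
#' @return Integer membership vector with attributes `"coassignment"` (the
#'   averaged matrix) and `"n_rep"`.
#' @export
consensus_communities <- function(g, n_rep = 1000L, tau = 0.9, seed = 1L) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  adj <- if (igraph::is_igraph(g)) igraph::graph_attr(g, "adjacency")
         else as.matrix(g)
  K <- nrow(adj)
  co <- matrix(0, K, K)
  for (b in seq_len(n_rep)) {
    memb <- louvain_directed(adj, seed = seed + b)
    co <- co + outer(memb, memb, `==`)
  }
  co <- co / n_rep
  B <- co >= tau
  gb <- igraph::graph_from_adjacency_matrix(B, mode = "undirected",
                                            diag = FALSE)
  memb <- igraph::components(gb)$membership
  memb <- match(memb, unique(memb))
  attr(memb, "coassignment") <- co
  attr(memb, "n_rep") <- as.integer(n_rep)
  memb
}
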