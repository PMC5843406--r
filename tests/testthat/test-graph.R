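test_that("graph construction mirrors the positive off-diagonal entries", {
  expect_equal(igraph::ecount(build_graph(transition_matrix(
    matrix(0, 4, 4), "thresholded"))), 0)

  set.seed(301)
  vals <- matrix(runif(25), 5, 5); diag(vals) <- 0
  vals[vals < 0.5] <- 0
  g <- build_graph(transition_matrix(vals, "thresholded"))
  expect_equal(igraph::ecount(g), sum(vals > 0))
  expect_equal(graph_density(g), sum(vals > 0) / (5 * 4))

  sym <- (vals + t(vals)); diag(sym) <- 0
  gs <- build_graph(transition_matrix(sym, "thresholded"))
  A <- as.matrix(igraph::as_adjacency_matrix(gs))
  expect_equal((A > 0), t(A > 0), ignore_attr = TRUE)
})

test_that("density arithmetic is E over K(K-1)", {
  vals <- matrix(0, 3, 3); vals[1, 2] <- 1; vals[2, 3] <- 1
  expect_equal(graph_density(build_graph(transition_matrix(vals, "thresholded"))),
               1 / 3)
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(graph_density(build_graph(transition_matrix(full, "thresholded"))),
               1)
})

test_that("symmetric toy graphs produce symmetric node metrics", {
  # 3-node directed cycle with unit weights
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  rep <- node_metrics(build_graph(transition_matrix(cyc, "thresholded")))
  expect_equal(rep$strength, rep(2, 3))
  expect_equal(diff(range(rep$betweenness)), 0)
  expect_equal(diff(range(rep$cpl)), 0)

  # 5-node star: center exchanges with every leaf
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1; star[2:5, 1] <- 1
  rep <- node_metrics(build_graph(transition_matrix(star, "thresholded")))
  expect_equal(which.max(rep$strength), 1L)
  expect_equal(which.max(rep$betweenness), 1L)
  expect_true(all(rep$betweenness[2:5] == 0))
})

test_that("distances and betweenness match the Floyd-Warshall oracle", {
  set.seed(311)
  for (rep_i in 1:8) {
    adj <- matrix(0, 10, 10)
    edges <- matrix(runif(100), 10, 10) < 0.3
    diag(edges) <- FALSE
    adj[edges] <- runif(sum(edges), 0.5, 1.5)
    if (sum(adj > 0) == 0) next
    g <- build_graph(transition_matrix(adj, "thresholded"))
    rep <- node_metrics(g)
    D <- fw_distances(adj)
    cpl_oracle <- apply(D + diag(NA, 10), 1, function(d) {
      fin <- d[is.finite(d) & !is.na(d)]
      if (length(fin) == 0) NA_real_ else mean(fin)
    })
    expect_equal(rep$cpl, unname(cpl_oracle), tolerance = 1e-9)
    expect_equal(rep$betweenness, fw_betweenness(adj), tolerance = 1e-7)
  }
})

test_that("directed weighted clustering is exact on the complete graph", {
  n <- 6
  full <- matrix(1, n, n); diag(full) <- 0
  rep <- node_metrics(build_graph(transition_matrix(full, "thresholded")))
  expect_equal(rep$clustering, rep(1, n), tolerance = 1e-12)

  # a two-edge path has no triangles
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 3] <- 1
  rep <- node_metrics(build_graph(transition_matrix(path, "thresholded")))
  expect_equal(rep$clustering, rep(0, 3))
})

test_that("node metrics are equivariant under node relabeling", {
  set.seed(321)
  adj <- matrix(0, 8, 8)
  edges <- matrix(runif(64), 8, 8) < 0.4; diag(edges) <- FALSE
  adj[edges] <- runif(sum(edges), 0.2, 2)
  perm <- sample(8)
  padj <- adj[perm, perm]                 # new node i = old node perm[i]
  r1 <- node_metrics(build_graph(transition_matrix(adj, "thresholded")))
  r2 <- node_metrics(build_graph(transition_matrix(padj, "thresholded")))
  for (col in c("strength", "betweenness", "cpl", "clustering")) {
    expect_equal(r2[[col]], r1[[col]][perm], tolerance = 1e-9)
  }
})

test_that("hub scoring counts percentile criteria with inclusive cutoffs", {
  set.seed(331)
  report <- data.frame(node = 1:40,
                       strength = sample(40), betweenness = sample(40),
                       cpl = sample(40), clustering = sample(40))
  scored <- hub_scores(report, pct = 20)
  expect_equal(sum(scored$strength >=
                     quantile(scored$strength, 0.8)), 8)
  # each criterion admits at least 20% of 40 = 8 nodes (no ties here)
  expect_equal(sum(scored$hub_score), 4 * 8)

  best <- data.frame(node = 1:5,
                     strength = c(10, 1, 2, 3, 4),
                     betweenness = c(10, 1, 2, 3, 4),
                     cpl = c(0.1, 2, 3, 4, 5),
                     clustering = c(0.01, 0.5, 0.6, 0.7, 0.8))
  expect_equal(hub_scores(best, 20)$hub_score[1], 4L)

  # monotonicity: raising strength and betweenness never lowers the score
  bumped <- best
  bumped$strength[2] <- 100; bumped$betweenness[2] <- 100
  expect_gte(hub_scores(bumped, 20)$hub_score[2],
             hub_scores(best, 20)$hub_score[2])
  expect_error(hub_scores(best, pct = 60), "pct")
})

test_that("a planted star center earns a hub score of at least 3", {
  set.seed(341)
  K <- 20
  adj <- matrix(0, K, K)
  sparse <- matrix(runif(K * K), K, K) < 0.06; diag(sparse) <- FALSE
  adj[sparse] <- runif(sum(sparse), 0.1, 0.3)
  adj[1, 2:K] <- runif(K - 1, 0.8, 1.2)    # strong bidirectional star
  adj[2:K, 1] <- runif(K - 1, 0.8, 1.2)
  rep <- hub_scores(node_metrics(build_graph(
    transition_matrix(adj, "thresholded"))))
  expect_gte(rep$hub_score[1], 3L)
})

test_that("directed Louvain recovers planted blocks and trivial partitions", {
  # two disconnected 5-cliques: deterministic 2-community consensus
  blk <- matrix(1, 5, 5); diag(blk) <- 0
  two <- rbind(cbind(blk, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), blk))
  memb <- consensus_communities(two, n_rep = 20, tau = 0.9, seed = 2)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:5])), 1)
  expect_equal(length(unique(memb[6:10])), 1)

  # complete uniform graph: a single community
  full <- matrix(1, 6, 6); diag(full) <- 0
  memb <- consensus_communities(full, n_rep = 20, tau = 0.9, seed = 3)
  expect_equal(length(unique(memb)), 1)

  # planted 3-block structure: exact recovery (adjusted Rand = 1)
  skip_if_not_installed("mclust")
  set.seed(351)
  truth <- rep(1:3, each = 5)
  adj <- matrix(0.05, 15, 15)
  for (b in 1:3) {
    idx <- which(truth == b)
    adj[idx, idx] <- 1
  }
  diag(adj) <- 0
  memb <- consensus_communities(adj, n_rep = 50, tau = 0.9, seed = 4)
  expect_equal(mclust::adjustedRandIndex(memb, truth), 1)
})

test_that("consensus membership is invariant to the replicate seed", {
  set.seed(361)
  truth <- rep(1:2, each = 6)
  adj <- matrix(0.02, 12, 12)
  for (b in 1:2) adj[truth == b, truth == b] <- 1
  diag(adj) <- 0
  m1 <- consensus_communities(adj, n_rep = 30, tau = 0.9, seed = 5)
  m2 <- consensus_communities(adj, n_rep = 30, tau = 0.9, seed = 99)
  expect_equal(as.integer(m1), as.integer(m2))
})
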