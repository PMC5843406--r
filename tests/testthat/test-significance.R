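test_that("consolidation collapses runs of repeated tokens", {
  expect_equal(consolidate(c(2L, 2L, 2L, 2L)), 2L)
  expect_equal(consolidate(c(1L, 1L, 2L, 2L, 1L)), c(1L, 2L, 1L))
  expect_equal(consolidate(c(0L, 0L, 3L, 0L)), c(0L, 3L, 0L))
  expect_equal(consolidate(integer(0)), integer(0))

  set.seed(201)
  s <- sample(0:3, 100, replace = TRUE)
  expect_equal(consolidate(consolidate(s)), consolidate(s))
})

test_that("consolidation never changes off-diagonal transition counts", {
  set.seed(211)
  for (rep in 1:15) {
    K <- sample(2:5, 1)
    labs <- sample(0:K, 120, replace = TRUE)
    expect_equal(unclass(count_transitions(labs, K = K)),
                 unclass(count_transitions(consolidate(labs), K = K)),
                 ignore_attr = TRUE)
  }
})

test_that("permutation p-values match exhaustive enumeration on 6 tokens", {
  tokens <- c(1L, 2L, 1L, 2L, 1L, 2L)   # already consolidated
  p_exact <- exhaustive_perm_p(tokens, K = 2)
  pr <- permutation_test(tokens, K = 2, n_perm = 4000, seed = 3)
  for (cell in list(c(1, 2), c(2, 1))) {
    pe <- p_exact[cell[1], cell[2]]
    mc_se <- sqrt(pe * (1 - pe) / pr$n_perm)
    expect_lt(abs(pr$p[cell[1], cell[2]] - pe), 4 * mc_se + 2 / pr$n_perm)
  }
  # the strictly alternating arrangement maximizes the raw 1->2 count, so
  # its count-share p is well below 1 while unobserved directions are at 1
  expect_lt(p_exact[1, 2], 0.5)

  # a second, asymmetric multiset (consolidated: no adjacent repeats)
  tokens <- c(1L, 2L, 3L, 1L, 2L, 3L)
  p_exact <- exhaustive_perm_p(tokens, K = 3)
  pr <- permutation_test(tokens, K = 3, n_perm = 4000, seed = 4)
  od <- row(p_exact) != col(p_exact)
  mc_se <- sqrt(pmax(p_exact[od], 1 / pr$n_perm) / pr$n_perm)
  expect_true(all(abs(pr$p[od] - p_exact[od]) < 5 * mc_se + 2 / pr$n_perm))
})

test_that("never-observed transitions get p = 1", {
  pr <- permutation_test(c(1L, 1L, 2L, 2L), K = 3, n_perm = 200, seed = 5)
  expect_equal(pr$p[1, 3], 1)
  expect_equal(pr$p[3, 1], 1)
  expect_equal(pr$p[2, 1], 1)   # 2 -> 1 never observed either
})

test_that("permutation null is stable across seeds within Monte-Carlo error", {
  set.seed(221)
  labs <- sample(1:4, 400, replace = TRUE)
  p1 <- permutation_test(labs, K = 4, n_perm = 1500, seed = 10)$p
  p2 <- permutation_test(labs, K = 4, n_perm = 1500, seed = 20)$p
  od <- row(p1) != col(p1)
  se <- sqrt(2 * pmax(p1[od], 0.01) / 1500)
  expect_true(all(abs(p1[od] - p2[od]) < 5 * se + 0.01))
})

test_that("permutations respect run boundaries", {
  # two runs whose concatenation would create a spurious adjacency
  runs <- list(c(1L, 2L, 1L, 2L), c(3L, 4L, 3L, 4L))
  pr <- permutation_test(runs, K = 4, n_perm = 500, seed = 6)
  # cross-run transitions are never observed nor producible by the null
  expect_equal(sum(pr$observed[1:2, 3:4]), 0)
  expect_equal(pr$p[2, 3], 1)
})

test_that("FDR thresholding zeroes non-survivors and rescales survivors", {
  # hand BH step-up over 6 p-values at q = 0.05:
  # sorted p = .001 .02 .04 .9 .9 .9; largest i with p_(i) <= 0.05 i/6
  # is i = 1 (.02 > .0167, .04 > .025), so only the smallest survives
  p <- matrix(1, 3, 3); diag(p) <- NA
  p[1, 2] <- 0.001; p[1, 3] <- 0.02; p[2, 1] <- 0.04
  p[2, 3] <- 0.9; p[3, 1] <- 0.9; p[3, 2] <- 0.9
  perm <- structure(list(p = p, n_perm = 1000L), class = "permutation_result")
  vals <- matrix(0, 3, 3); vals[1, 2] <- 8; vals[1, 3] <- 5; vals[2, 1] <- 3
  g <- transition_matrix(vals)
  expect_warning(thr <- threshold_matrix(g, perm, q = 0.05), NA)
  surv <- attr(thr, "survivors")
  expect_equal(which(surv), which(p == 0.001))
  expect_equal(thr[1, 2], 1)           # lone survivor rescales to 1
  expect_equal(sum(thr > 0), 1)

  # four p-values by hand: {.001, .02, .04, .9} against BH thresholds
  # .0125 .025 .0375 .05 -> largest i passing is 2, first two survive
  expect_equal(which(p.adjust(c(0.001, 0.02, 0.04, 0.9), "BH") <= 0.05),
               c(1L, 2L))

  expect_error(threshold_matrix(g, perm, q = 1), "q must be")
  p_all1 <- p; p_all1[!is.na(p_all1)] <- 1
  perm1 <- structure(list(p = p_all1, n_perm = 1000L),
                     class = "permutation_result")
  expect_warning(empty <- threshold_matrix(g, perm1, q = 0.05),
                 "no transition survives")
  expect_equal(sum(empty), 0)
})

test_that("planted strong transitions survive, absent ones do not", {
  # 5-state cycle-like chain: i -> i+1 or i+2 with probability 1/2 each
  K <- 5
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    P[i, (i %% K) + 1] <- 0.5
    P[i, ((i + 1) %% K) + 1] <- 0.5
  }
  labs <- generate_label_chain(P, 5000, seed = 231)
  pr <- permutation_test(labs, K = K, n_perm = 1000, seed = 7)
  g <- normalize01(count_transitions(labs, K = K))
  thr <- threshold_matrix(g, pr, q = 0.05)
  surv <- attr(thr, "survivors")
  planted <- P > 0
  expect_true(all(surv[planted]))
  od <- row(P) != col(P)
  expect_false(any(surv[od & !planted]))
  expect_true(all(thr[surv] > 0))
})

test_that("thresholded similarity regression floors negative residuals", {
  set.seed(241)
  K <- 4
  labs <- sample(1:K, 3000, replace = TRUE)
  pr <- permutation_test(labs, K = K, n_perm = 300, seed = 8)
  g <- normalize01(count_transitions(labs, K = K))
  sim <- pattern_similarity(generate_patterns(K, 80, overlap = 0.3,
                                              seed = 11))
  thr <- threshold_matrix(g, pr, q = 0.9, sim = sim)  # permissive q
  surv <- attr(thr, "survivors")
  if (any(surv)) expect_true(all(thr[surv] >= 1e-6))
  expect_true(all(thr[!surv] == 0))
})
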