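test_that("transition counting ignores dwell and 0-involving pairs", {
  m <- count_transitions(c(1L, 1L, 2L, 0L, 2L, 3L), K = 3)
  expected <- matrix(0, 3, 3)
  expected[1, 2] <- 1; expected[2, 3] <- 1
  expect_equal(unclass(m), expected, ignore_attr = TRUE)

  expect_equal(sum(count_transitions(rep(0L, 10), K = 4)), 0)

  m <- count_transitions(c(1L, 2L, 1L, 2L, 1L), K = 2)
  expect_equal(m[1, 2], 2)
  expect_equal(m[2, 1], 2)

  expect_error(count_transitions(c(1L, 5L), K = 3), "label error")
})

test_that("counting agrees with a naive scan on random sequences", {
  set.seed(101)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    labs <- sample(0:K, 80, replace = TRUE)
    expect_equal(unclass(count_transitions(labs, K = K)),
                 naive_counts(labs, K), ignore_attr = TRUE)
  }
})

test_that("counting is equivariant under label permutation", {
  set.seed(111)
  K <- 5
  labs <- sample(0:K, 200, replace = TRUE)
  perm <- sample(K)
  relabeled <- labs
  relabeled[labs > 0L] <- perm[labs[labs > 0L]]
  m1 <- unclass(count_transitions(labs, K = K))
  m2 <- unclass(count_transitions(relabeled, K = K))
  expect_equal(m2[perm, perm], m1, ignore_attr = TRUE)
})

test_that("aggregation sums or averages entrywise and checks shapes", {
  m1 <- count_transitions(c(1L, 2L, 3L, 1L), K = 3)
  m2 <- count_transitions(c(3L, 2L, 1L, 2L), K = 3)
  expect_equal(unclass(aggregate_transitions(list(m1, m1), "mean")),
               unclass(m1), ignore_attr = TRUE)
  s <- aggregate_transitions(list(m1, m2), "sum")
  expect_equal(sum(s), sum(m1) + sum(m2))
  expect_error(aggregate_transitions(list(), "sum"), "empty")
  expect_error(aggregate_transitions(
    list(m1, count_transitions(1:2, K = 2)), "sum"), "mixed size")
})

test_that("run-wise counting loses no valid adjacent pair", {
  set.seed(121)
  K <- 4
  runs <- lapply(1:6, function(r) sample(0:K, 100, replace = TRUE))
  total <- sum(aggregate_transitions(
    lapply(runs, count_transitions, K = K), "sum"))
  direct <- sum(vapply(runs, function(labs) {
    from <- labs[-length(labs)]; to <- labs[-1]
    sum(from != 0 & to != 0 & from != to)
  }, numeric(1)))
  expect_equal(total, direct)
})

test_that("min-max normalization maps the off-diagonal to [0, 1]", {
  vals <- matrix(0, 3, 3)
  vals[1, 2] <- 0; vals[1, 3] <- 5; vals[2, 1] <- 10
  vals[2, 3] <- 5; vals[3, 1] <- 0; vals[3, 2] <- 10
  m <- normalize01(transition_matrix(vals))
  expect_equal(sort(unique(off <- m[row(m) != col(m)])), c(0, 0.5, 1))
  expect_equal(attr(m, "level"), "normalized")

  # already [0, 1] with min 0 and max 1: unchanged
  expect_equal(unclass(normalize01(m)), unclass(m), ignore_attr = TRUE)

  const <- transition_matrix(matrix(1, 2, 2) - diag(2))
  expect_warning(z <- normalize01(const), "constant")
  expect_equal(sum(z), 0)

  expect_error(normalize01(transition_matrix(matrix(0, 3, 3))),
               "degenerate")
})

test_that("similarity regression removes the linear component", {
  sim <- diag(3)
  sim[1, 2] <- sim[2, 1] <- 0.5
  sim[1, 3] <- sim[3, 1] <- -0.2
  sim[2, 3] <- sim[3, 2] <- 0.1
  # matrix exactly affine in similarity: residuals vanish
  vals <- 2 + 3 * sim; diag(vals) <- 0
  res <- regress_similarity(transition_matrix(vals, "normalized"), sim)
  expect_lt(max(abs(off_d <- res[row(res) != col(res)])), 1e-10)

  # OLS identity: residuals orthogonal to the regressor
  set.seed(131)
  vals <- matrix(runif(9), 3, 3); diag(vals) <- 0
  res <- regress_similarity(transition_matrix(vals, "normalized"), sim)
  od <- row(res) != col(res)
  expect_lt(abs(sum(res[od] * sim[od])), 1e-8)
  expect_lt(abs(sum(res[od])), 1e-8)

  # 6-point hand OLS
  y <- vals[od]; x <- sim[od]
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(res[od], y - alpha - beta * x, tolerance = 1e-12)

  expect_error(regress_similarity(transition_matrix(vals, "normalized"),
                                  matrix(1, 3, 3)), "degenerate regressor")
})

test_that("split-half reproducibility behaves at both extremes", {
  m1 <- count_transitions(c(1L, 2L, 3L, 1L, 3L), K = 3)
  m2 <- count_transitions(c(3L, 1L, 2L, 3L, 2L), K = 3)
  # identical subgroups correlate perfectly
  r <- split_half_reproducibility(list(m1, m2, m1, m2),
                                  c("A", "A", "B", "B"))
  expect_equal(as.numeric(r), 1, tolerance = 1e-12)
  expect_error(split_half_reproducibility(list(m1, m2), c("A", "A")),
               "nonempty")

  # shared planted structure at a 20/20 split
  P <- default_transition_probs(8, seed = 33)
  cohort <- make_cohort(40, 600, P, seed = 141)
  grp <- rep(c("A", "B"), 20)
  r_shared <- split_half_reproducibility(cohort, grp)
  expect_gte(as.numeric(r_shared), 0.8)

  # independent planted structures decorrelate at K = 40
  Pa <- default_transition_probs(40, seed = 1)
  Pb <- default_transition_probs(40, seed = 2)
  ca <- make_cohort(10, 2000, Pa, seed = 151)
  cb <- make_cohort(10, 2000, Pb, seed = 251)
  r_ind <- split_half_reproducibility(c(ca, cb), rep(c("A", "B"), each = 10))
  expect_lt(abs(as.numeric(r_ind)), 0.2)
})

test_that("individual reproducibility averages on the Fisher-z scale", {
  P <- default_transition_probs(6, seed = 5)
  cohort <- make_cohort(6, 400, P, seed = 161)
  group <- normalize01(aggregate_transitions(cohort, "mean"))
  ir <- individual_reproducibility(cohort, group)
  r_hand <- vapply(cohort, function(m)
    cor(m[row(m) != col(m)], group[row(group) != col(group)]), numeric(1))
  expect_equal(ir$mean, tanh(mean(atanh(r_hand))), tolerance = 1e-10)
  expect_equal(ir$sd, sd(r_hand), tolerance = 1e-10)

  # subject matrices equal to the group matrix: mean at the clip ceiling
  same <- individual_reproducibility(list(group, group), group)
  expect_gt(same$mean, 1 - 1e-6)

  # matrices independent of the group matrix: mean near zero
  other <- make_cohort(30, 400, default_transition_probs(6, seed = 99),
                       seed = 171)
  null_ir <- individual_reproducibility(
    other, normalize01(aggregate_transitions(cohort, "mean")))
  expect_lt(abs(null_ir$mean), 0.25)
})
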