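#' Configuration for a synthetic co-activation dataset
#'
#' Bundles and validates the parameters of the synthetic generator. The
#' generator plants a first-order Markov chain over `K` spatial patterns:
#' every frame of every run is one pattern plus i.i.d. Gaussian noise, so the
#' whole pipeline (matching, transition counting, permutation testing, graph
#' analysis) can be exercised against a known ground truth.
#'
#' @param n_patterns Number of reference patterns `K` (>= 2, or 1 for
#'   degenerate edge cases).
#' @param n_voxels Number of voxels `V` per frame (>= `n_patterns`).
#' @param n_subjects Number of subjects in the cohort.
#' @param runs_per_subject Runs acquired per subject.
#' @param frames_per_run Frames `T` per run (>= 2).
#' @param transition_probs `K x K` row-stochastic matrix; the diagonal is the
#'   dwell probability. Default: dwell 0.8 with each state preferring 3
#'   target states (sparse structured off-diagonal), mimicking the sparse,
#'   sequence-specific transition structure the analysis is designed to
#'   detect.
#' @param pattern_overlap Fraction in `[0, 1)` controlling shared variance
#'   between pattern maps; 0 gives near-orthogonal maps.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   signal units (pattern maps have unit variance).
#' @param censor_rate Fraction in `[0, 1)` of frames randomly flagged as
#'   censored (emulating preprocessing removals unrelated to motion).
#' @param fd_spike_prob Per-frame probability of a motion spike (FD drawn
#'   above the 0.2 mm censoring threshold).
#' @param seed Integer seed; the whole dataset is reproducible given the
#'   configuration.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_patterns = 8L, n_voxels = 300L,
                             n_subjects = 4L, runs_per_subject = 2L,
                             frames_per_run = 600L,
                             transition_probs = NULL,
                             pattern_overlap = 0, noise_sd = 0.5,
                             censor_rate = 0, fd_spike_prob = 0.02,
                             seed = 1L) {
  K <- as.integer(n_patterns)
  if (is.na(K) || K < 1L)
    stop("invalid configuration: n_patterns must be a positive integer")
  if (n_voxels < K)
    stop("invalid configuration: n_voxels must be >= n_patterns")
  if (frames_per_run < 2L)
    stop("invalid configuration: frames_per_run must be >= 2")
  if (noise_sd < 0)
    stop("invalid configuration: noise_sd must be >= 0")
  if (pattern_overlap < 0 || pattern_overlap >= 1)
    stop("invalid configuration: pattern_overlap must be in [0, 1)")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("invalid configuration: censor_rate must be in [0, 1)")
  if (is.null(transition_probs))
    transition_probs <- default_transition_probs(K, seed = seed)
  check_row_stochastic(transition_probs, K)
  cfg <- list(n_patterns = K,
              n_voxels = as.integer(n_voxels),
              n_subjects = as.integer(n_subjects),
              runs_per_subject = as.integer(runs_per_subject),
              frames_per_run = as.integer(frames_per_run),
              transition_probs = transition_probs,
              pattern_overlap = pattern_overlap,
              noise_sd = noise_sd,
              censor_rate = censor_rate,
              fd_spike_prob = fd_spike_prob,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

check_row_stochastic <- function(P, K = nrow(P)) {
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stop("invalid configuration: transition_probs must be a K x K matrix")
  if (any(P < 0))
    stop("invalid configuration: transition probabilities must be >= 0")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("invalid configuration: transition_probs rows must each sum to 1")
  invisible(P)
}

#' Default planted transition structure
#'
#' Row-stochastic `K x K` matrix with dwell probability `dwell` on the
#' diagonal and the remaining mass spread over a few preferred target
#' states per row: the off-diagonal part is a weighted mixture of random
#' derangements (permutations without fixed points), so some ordered
#' transitions are strongly favored, most are absent, and the matrix is
#' doubly stochastic. Double stochasticity gives the chain a uniform
#' stationary distribution, so observed transition counts are proportional
#' to the planted probabilities themselves rather than to
#' occupancy-weighted probabilities.
#'
#' @param K Number of states.
#' @param dwell Diagonal (stay) probability.
#' @param weights Relative weights of the derangement layers (their number
#'   sets the targets per state).
#' @param seed Integer seed for the random derangements.
#' @return A `K x K` row-stochastic (indeed doubly stochastic) matrix.
#' @export
default_transition_probs <- function(K, dwell = 0.8,
                                     weights = c(0.5, 0.3, 0.2),
                                     seed = 1L) {
  if (K == 1L) return(matrix(1, 1, 1))
  rs <- local_rng(seed + 7129L)
  derangement <- function() {
    repeat {
      p <- rs$sample(K, K)
      if (all(p != seq_len(K))) return(p)
    }
  }
  if (K == 2L) weights <- weights[1]   # only one derangement exists
  weights <- weights / sum(weights)
  P <- matrix(0, K, K)
  for (l in seq_along(weights)) {
    perm <- derangement()
    P[cbind(seq_len(K), perm)] <- P[cbind(seq_len(K), perm)] +
      (1 - dwell) * weights[l]
  }
  diag(P) <- dwell
  P
}

# Small private RNG stream: evaluates expressions under a local seed without
# disturbing the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(sample = function(x, size, replace = FALSE, prob = NULL)
         with_state(function() sample(x, size, replace = replace, prob = prob)),
       runif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max)),
       rnorm = function(n, mean = 0, sd = 1) with_state(function() rnorm(n, mean, sd)))
}

#' Generate K ground-truth spatial pattern maps
#'
#' Each map has a dedicated block of voxels carrying independent Gaussian
#' loadings plus a small shared background; with `overlap > 0` a common
#' spatial component is mixed in so the expected pairwise spatial correlation
#' grows with `overlap`. Maps are standardized to zero mean and unit
#' variance over voxels.
#'
#' @param K Number of patterns.
#' @param V Number of voxels (>= `K`).
#' @param overlap Fraction in `[0, 1)`: variance share of the common
#'   component.
#' @param seed Integer seed.
#' @return `K x V` numeric matrix with attribute `"support"`: the per-voxel
#'   block assignment in `1..K` (an implicit parcellation of the voxel grid).
#' @export
generate_patterns <- function(K, V, overlap = 0, seed = 1L) {
  if (V < K) stop("invalid configuration: V must be >= K")
  if (overlap < 0 || overlap >= 1)
    stop("invalid configuration: overlap must be in [0, 1)")
  rs <- local_rng(seed + 551L)
  block <- rep(seq_len(K), length.out = V)
  block <- sort(block)
  maps <- matrix(rs$rnorm(K * V, sd = 0.01), K, V)   # faint shared-free background
  for (k in seq_len(K)) {
    idx <- which(block == k)
    maps[k, idx] <- rs$rnorm(length(idx))
  }
  if (overlap > 0) {
    shared <- rs$rnorm(V)
    maps <- sqrt(1 - overlap) * maps + sqrt(overlap) *
      matrix(shared, K, V, byrow = TRUE)
  }
  maps <- maps - rowMeans(maps)
  maps <- maps / apply(maps, 1, stats::sd)
  attr(maps, "support") <- block
  maps
}

#' Simulate a first-order Markov label chain
#'
#' The initial state is uniform over `1..K`; each subsequent state is drawn
#' from the row of `P` indexed by the current state.
#'
#' @param P `K x K` row-stochastic transition matrix.
#' @param T_len Number of frames.
#' @param seed Integer seed.
#' @return Integer vector of length `T_len` with values in `1..K`.
#' @export
generate_label_chain <- function(P, T_len, seed = 1L) {
  check_row_stochastic(P)
  K <- nrow(P)
  rs <- local_rng(seed + 9041L)
  u <- rs$runif(T_len)
  s <- integer(T_len)
  cum <- t(apply(P, 1, cumsum))
  s[1] <- 1L + findInterval(u[1], seq_len(K - 1) / K) # uniform initial state
  if (K == 1L) s[1] <- 1L
  for (t in seq_len(T_len - 1L)) {
    s[t + 1L] <- 1L + sum(u[t + 1L] > cum[s[t], -K])
  }
  s
}

#' Seed parcellation from ground-truth pattern maps
#'
#' Derives a parcel atlas for seed-based library building: parcel `k` is
#' the strongly positive core of pattern `k`'s support block (loadings at
#' or above the block's `1 - core_frac` quantile), so the parcel-averaged
#' time course rises whenever pattern `k` is the active state -- the same
#' role a functional parcel's seed time course plays in real data.
#' Remaining voxels are background (label 0).
#'
#' @param patterns `K x V` pattern maps carrying a `"support"` attribute
#'   (as produced by [generate_patterns()]).
#' @param core_frac Fraction of each block assigned to the seed core.
#' @return Integer vector of per-voxel labels in `0..K`.
#' @export
seed_atlas <- function(patterns, core_frac = 0.4) {
  support <- attr(patterns, "support")
  if (is.null(support)) stop("patterns carry no support attribute")
  K <- nrow(patterns)
  atlas <- integer(ncol(patterns))
  for (k in seq_len(K)) {
    idx <- which(support == k)
    cut <- stats::quantile(patterns[k, idx], 1 - core_frac, names = FALSE)
    atlas[idx[patterns[k, idx] >= cut]] <- k
  }
  atlas
}

#' Render a full synthetic multi-subject dataset
#'
#' For every run, draws a Markov label chain, renders each frame as its
#' pattern map plus Gaussian noise, and simulates a framewise-displacement
#' trace: half-normal baseline `|N(0.04, 0.02)|` mm with spikes above the
#' 0.2 mm censoring threshold at rate `fd_spike_prob`. Additional frames are
#' randomly flagged censored at rate `censor_rate`. Bit-identical for a
#' given configuration.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `time_series` (list of `T x V` matrices), `true_labels`, `motion`
#'   (FD in mm, first frame 0), `extra_censor` (logical), `patterns`
#'   (`K x V`), `atlas` (per-voxel parcel label from the pattern supports),
#'   `run_info` (data.frame with `subject`, `run`), and `config`.
#' @export
render_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- config$n_patterns; V <- config$n_voxels
  T_len <- config$frames_per_run
  patterns <- generate_patterns(K, V, config$pattern_overlap, config$seed)
  n_runs <- config$n_subjects * config$runs_per_subject
  run_info <- data.frame(
    subject = rep(seq_len(config$n_subjects), each = config$runs_per_subject),
    run = rep(seq_len(config$runs_per_subject), times = config$n_subjects))
  rs <- local_rng(config$seed)
  time_series <- vector("list", n_runs)
  true_labels <- vector("list", n_runs)
  motion <- vector("list", n_runs)
  extra_censor <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    labs <- generate_label_chain(config$transition_probs, T_len,
                                 seed = config$seed + 131L * r)
    ts <- patterns[labs, , drop = FALSE]
    if (config$noise_sd > 0)
      ts <- ts + matrix(rs$rnorm(T_len * V, sd = config$noise_sd), T_len, V)
    fd <- abs(rs$rnorm(T_len, mean = 0.04, sd = 0.02))
    spikes <- rs$runif(T_len) < config$fd_spike_prob
    fd[spikes] <- 0.25 + rs$runif(sum(spikes), 0, 0.35)
    fd[1] <- 0
    cen <- rs$runif(T_len) < config$censor_rate
    time_series[[r]] <- ts
    true_labels[[r]] <- labs
    motion[[r]] <- fd
    extra_censor[[r]] <- cen
  }
  out <- list(time_series = time_series, true_labels = true_labels,
              motion = motion, extra_censor = extra_censor,
              patterns = patterns, atlas = seed_atlas(patterns),
              run_info = run_info, config = config)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic_dataset: %d subjects x %d runs x %d frames, K=%d patterns, V=%d voxels\n",
              cfg$n_subjects, cfg$runs_per_subject, cfg$frames_per_run,
              cfg$n_patterns, cfg$n_voxels))
  invisible(x)
}
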