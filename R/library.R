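#' Reference pattern library
#'
#' Container for the `K` characteristic RSFC maps that define the matching
#' alphabet, together with their pairwise spatial similarity.
#'
#' @param maps `K x V` matrix of group-level statistic maps (t or z values
#'   per voxel).
#' @param similarity Optional `K x K` similarity matrix; computed with
#'   [pattern_similarity()] when omitted.
#' @param seed_ids Optional identifiers of the seed parcels (default
#'   `1..K`).
#' @return An object of class `pattern_library`.
#' @export
pattern_library <- function(maps, similarity = NULL, seed_ids = NULL) {
  maps <- as.matrix(maps)
  K <- nrow(maps)
  if (is.null(similarity)) similarity <- pattern_similarity(maps)
  stopifnot(nrow(similarity) == K, ncol(similarity) == K)
  if (is.null(seed_ids)) seed_ids <- seq_len(K)
  out <- list(maps = maps, similarity = similarity, seed_ids = seed_ids,
              K = K, V = ncol(maps))
  class(out) <- "pattern_library"
  out
}

#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("pattern_library: K=%d reference maps over V=%d voxels\n",
              x$K, x$V))
  od <- x$similarity[row(x$similarity) != col(x$similarity)]
  cat(sprintf("  mean |off-diagonal spatial similarity| = %.3f\n",
              mean(abs(od))))
  invisible(x)
}

#' Seed-based correlation map for one parcel
#'
#' Averages the time courses of all voxels in the seed parcel, correlates
#' the seed time course with every voxel, and Fisher z-transforms the
#' correlations (clipped at `|r| = 1 - 1e-7` so `atanh` stays finite).
#' Zero-variance voxels get z = 0 and are flagged. When the run is longer
#' than `max_frames`, only the first `max_frames` retained frames enter the
#' correlation so every run contributes the same degrees of freedom.
#'
#' @param ts `T x V` (preprocessed) time-series matrix.
#' @param atlas Integer vector of length `V`, labels in `0..K` (0 =
#'   background).
#' @param parcel Seed parcel id in `1..K`.
#' @param keep Optional logical vector of frames to retain (e.g.
#'   `frame_mask$keep`).
#' @param max_frames Per-run frame cap (default 540; `Inf` to disable).
#' @return Numeric vector of length `V` of Fisher z values, with attribute
#'   `"flagged"` marking zero-variance voxels.
#' @export
seed_rsfc_map <- function(ts, atlas, parcel, keep = NULL, max_frames = 540) {
  ts <- as.matrix(ts)
  if (length(atlas) != ncol(ts))
    stop("format error: atlas length must equal the number of voxels")
  idx <- which(atlas == parcel)
  if (length(idx) == 0) stop("atlas error: parcel ", parcel, " is empty")
  if (!is.null(keep)) ts <- ts[keep, , drop = FALSE]
  if (nrow(ts) > max_frames) ts <- ts[seq_len(max_frames), , drop = FALSE]
  if (nrow(ts) < 3) stop("format error: need at least 3 retained frames")
  seed_tc <- rowMeans(ts[, idx, drop = FALSE])
  sds <- apply(ts, 2, stats::sd)
  flagged <- sds == 0 | stats::sd(seed_tc) == 0
  r <- rep(0, ncol(ts))
  if (stats::sd(seed_tc) > 0)
    r[!flagged] <- as.vector(stats::cor(seed_tc, ts[, !flagged, drop = FALSE]))
  if (any(flagged))
    warning("zero-variance voxels set to z = 0 (", sum(flagged), " flagged)")
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[flagged] <- 0
  attr(z, "flagged") <- flagged
  z
}

#' Group-level statistic map across runs and subjects
#'
#' Voxelwise test of mean Fisher z against zero, with subject treated as a
#' random effect. The default method averages each subject's runs and
#' performs a one-sample t-test on the per-subject means, which coincides
#' with the random-intercept linear mixed model for balanced designs;
#' `method = "lmm"` fits the full model per voxel with lme4.
#'
#' @param z_maps `n_runs x V` matrix (or list of length-V vectors) of
#'   per-run Fisher z maps.
#' @param subject_of_run Integer/factor of length `n_runs` mapping runs to
#'   subjects.
#' @param method `"subject_mean"` (default) or `"lmm"`.
#' @param se_floor_quantile In `[0, 1)`: when positive, voxelwise standard
#'   errors are floored at this quantile of the positive SEs across voxels
#'   before forming t. This variance moderation keeps near-noiseless
#'   voxels from dominating the map through vanishing denominators; 0
#'   (default) gives the plain statistic. Applies to `"subject_mean"`
#'   only.
#' @return Numeric vector of length `V`: the t statistic per voxel.
#' @export
group_map <- function(z_maps, subject_of_run,
                      method = c("subject_mean", "lmm"),
                      se_floor_quantile = 0) {
  method <- match.arg(method)
  if (is.list(z_maps)) z_maps <- do.call(rbind, z_maps)
  z_maps <- as.matrix(z_maps)
  subject_of_run <- as.factor(subject_of_run)
  if (length(subject_of_run) != nrow(z_maps))
    stop("format error: one subject id per run is required")
  n_subj <- nlevels(subject_of_run)
  if (n_subj < 2) stop("degenerate model: need at least 2 subjects")
  if (method == "subject_mean") {
    means <- rowsum(z_maps, subject_of_run) /
      as.vector(table(subject_of_run))
    mu <- colMeans(means)
    se <- apply(means, 2, stats::sd) / sqrt(n_subj)
    if (se_floor_quantile > 0 && any(se > 0)) {
      floor_se <- stats::quantile(se[se > 0], se_floor_quantile,
                                  names = FALSE)
      se <- pmax(se, floor_se)
    }
    t_stat <- mu / se
    t_stat[se == 0] <- ifelse(mu[se == 0] == 0, 0,
                              sign(mu[se == 0]) * Inf)
    t_stat
  } else {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method 'lmm' requires the lme4 package")
    subj <- subject_of_run
    apply(z_maps, 2, function(z) {
      if (stats::sd(z) == 0) return(if (z[1] == 0) 0 else sign(z[1]) * Inf)
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(z ~ 1 + (1 | subj),
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      cf <- stats::coef(summary(fit))
      cf[1, "Estimate"] / cf[1, "Std. Error"]
    })
  }
}

#' Pairwise spatial similarity between pattern maps
#'
#' Pearson correlation over voxels for every pair of maps. Constant maps
#' are flagged; their similarity entries are set to 0 (diagonal stays 1).
#'
#' @param maps `K x V` matrix of maps.
#' @return `K x K` symmetric correlation matrix with unit diagonal and
#'   attribute `"flagged"` marking constant maps.
#' @export
pattern_similarity <- function(maps) {
  maps <- as.matrix(maps)
  K <- nrow(maps)
  sds <- apply(maps, 1, stats::sd)
  flagged <- sds == 0
  sim <- diag(1, K)
  ok <- which(!flagged)
  if (length(ok) >= 2) {
    sim_ok <- stats::cor(t(maps[ok, , drop = FALSE]))
    sim[ok, ok] <- sim_ok
  }
  diag(sim) <- 1
  if (any(flagged))
    warning("constant maps flagged; their similarity entries set to 0")
  attr(sim, "flagged") <- flagged
  sim
}

#' Build the full reference library from multi-run data
#'
#' Convenience wrapper chaining [seed_rsfc_map()] over all parcels and runs,
#' [group_map()] across runs/subjects, and [pattern_similarity()].
#'
#' @param runs List of `T x V` time-series matrices.
#' @param atlas Integer per-voxel parcel labels in `0..K`.
#' @param subject_of_run Subject id per run.
#' @param keep Optional list of logical keep-vectors, one per run.
#' @param max_frames Per-run frame cap passed to [seed_rsfc_map()].
#' @param method Group statistic method, see [group_map()].
#' @param se_floor_quantile Variance moderation for the group t map
#'   (default 0.5: SEs floored at their median across voxels), see
#'   [group_map()].
#' @return A [pattern_library()].
#' @export
build_pattern_library <- function(runs, atlas, subject_of_run, keep = NULL,
                                  max_frames = 540,
                                  method = "subject_mean",
                                  se_floor_quantile = 0.5) {
  K <- max(atlas)
  if (!all(seq_len(K) %in% atlas))
    stop("atlas error: every label 1..K must occur at least once")
  maps <- matrix(NA_real_, K, length(atlas))
  for (k in seq_len(K)) {
    z <- lapply(seq_along(runs), function(r)
      seed_rsfc_map(runs[[r]], atlas, k,
                    keep = if (is.null(keep)) NULL else keep[[r]],
                    max_frames = max_frames))
    maps[k, ] <- group_map(do.call(rbind, z), subject_of_run,
                           method = method,
                           se_floor_quantile = se_floor_quantile)
  }
  pattern_library(maps, seed_ids = seq_len(K))
}
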