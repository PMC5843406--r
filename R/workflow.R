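#' Run the full transition-analysis pipeline
#'
#' End-to-end orchestration on a dataset with known run structure: motion
#' scrubbing, reference-library construction (seed maps, group statistics,
#' pairwise similarity), frame matching, transition counting and
#' aggregation, permutation testing with FDR thresholding, graph
#' construction with consensus communities and hub scores, motion-control
#' analyses, and reproducibility summaries. All stage outputs are written
#' to `out_dir` as delimited text together with a parameter log, and the
#' full set of in-memory results is returned invisibly.
#'
#' @param data A `synthetic_dataset` (see [render_dataset()]) or a list
#'   with elements `time_series` (list of `T x V` matrices), `atlas`
#'   (per-voxel labels `0..K`), `motion` (list of FD vectors), `run_info`
#'   (data.frame with a `subject` column), and optionally `extra_censor`.
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param fd_threshold FD censoring threshold in mm (default 0.2).
#' @param n_initial Leading frames discarded per run (default 10).
#' @param min_r Minimal match correlation (default 0.1).
#' @param max_frames Per-run frame cap for seed maps (default 540).
#' @param n_perm Permutations for the transition null (default 10000).
#' @param q FDR rate (default 0.05).
#' @param louvain_reps Louvain repetitions for the consensus (default
#'   1000).
#' @param tau Co-assignment binarization threshold (default 0.9).
#' @param hub_pct Hub percentile (default 20).
#' @param seed Integer seed for permutations, community detection, and
#'   the random split-half.
#' @param n_random_splits Random splits in the motion-control comparison
#'   (default 1000).
#' @return (Invisibly) a list with components `library`, `masks`, `seqs`,
#'   `per_subject`, `group_raw`, `group_norm`, `group_resid`, `perm`,
#'   `thresholded`, `graph`, `report`, `communities`, `reproducibility`,
#'   `motion`, and `params`.
#' @export
run_pipeline <- function(data, out_dir = NULL,
                         fd_threshold = 0.2, n_initial = 10L,
                         min_r = 0.1, max_frames = 540,
                         n_perm = 10000L, q = 0.05,
                         louvain_reps = 1000L, tau = 0.9, hub_pct = 20,
                         seed = 1L, n_random_splits = 1000L) {
  if (q <= 0 || q >= 1) stop("invalid configuration: q must be in (0, 1)")
  if (fd_threshold <= 0)
    stop("invalid configuration: fd_threshold must be > 0")
  runs <- data$time_series
  atlas <- data$atlas
  motion <- data$motion
  run_info <- data$run_info
  n_runs <- length(runs)
  stopifnot(length(motion) == n_runs, nrow(run_info) == n_runs)
  subj <- run_info$subject
  K <- max(atlas)

  # --- motion scrubbing -------------------------------------------------
  masks <- lapply(seq_len(n_runs), function(r) {
    m <- scrub_frames(motion[[r]], threshold = fd_threshold,
                      n_initial = n_initial)
    if (!is.null(data$extra_censor)) {
      extra <- data$extra_censor[[r]] & m$keep
      m$keep[extra] <- FALSE
      m$reason[extra] <- "unmatched"
    }
    m
  })

  # --- reference library ------------------------------------------------
  keep <- lapply(masks, `[[`, "keep")
  library <- build_pattern_library(runs, atlas, subj, keep = keep,
                                   max_frames = max_frames)

  # --- frame matching ---------------------------------------------------
  seqs <- lapply(seq_len(n_runs), function(r)
    match_frames(normalize_frames(runs[[r]]), library, mask = masks[[r]],
                 min_r = min_r))

  # --- transition matrices ----------------------------------------------
  per_subject <- subject_matrices(seqs, subj, K = K)
  group_raw <- aggregate_transitions(per_subject, mode = "mean")
  group_norm <- normalize01(group_raw)
  group_resid <- regress_similarity(group_norm, library$similarity)

  # --- permutation null, FDR threshold ----------------------------------
  perm <- permutation_test(seqs, K = K, n_perm = n_perm, seed = seed)
  thresholded <- threshold_matrix(group_norm, perm, q = q,
                                  sim = library$similarity)

  # --- graph analysis ---------------------------------------------------
  graph <- build_graph(thresholded)
  if (igraph::ecount(graph) > 0) {
    report <- hub_scores(node_metrics(graph), pct = hub_pct)
    communities <- consensus_communities(graph, n_rep = louvain_reps,
                                         tau = tau, seed = seed)
    report$community <- communities[report$node]
  } else {
    report <- NULL
    communities <- NULL
  }

  # --- reproducibility --------------------------------------------------
  n_subj <- length(per_subject)
  repro <- list()
  if (n_subj >= 4) {
    rs <- local_rng(seed + 17L)
    half <- rs$sample(n_subj, floor(n_subj / 2))
    grp <- factor(ifelse(seq_len(n_subj) %in% half, "A", "B"))
    repro$split_half <- as.numeric(
      split_half_reproducibility(per_subject, grp))
    repro$split_half_regressed <- as.numeric(
      split_half_reproducibility(per_subject, grp, regress = TRUE,
                                 sim = library$similarity))
  }
  repro$individual <- individual_reproducibility(per_subject, group_norm)

  # --- motion controls --------------------------------------------------
  fd_mean_subj <- vapply(split(unlist(motion), rep(subj, lengths(motion))),
                         mean, numeric(1))
  motion_res <- list(
    frame_fd = transition_frame_fd(seqs, motion),
    fd_matrix = transition_fd_matrix(seqs, motion, K = K))
  if (n_subj >= 4)
    motion_res$split_test <- motion_split_test(per_subject, fd_mean_subj,
                                               n_random = n_random_splits,
                                               seed = seed + 29L)

  params <- list(K = K, fd_threshold = fd_threshold,
                 n_initial = n_initial, min_r = min_r,
                 max_frames = max_frames, n_perm = n_perm, q = q,
                 louvain_reps = louvain_reps, tau = tau,
                 hub_pct = hub_pct, seed = seed)
  result <- list(library = library, masks = masks, seqs = seqs,
                 per_subject = per_subject, group_raw = group_raw,
                 group_norm = group_norm, group_resid = group_resid,
                 perm = perm, thresholded = thresholded, graph = graph,
                 report = report, communities = communities,
                 reproducibility = repro, motion = motion_res,
                 params = params)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.table(result$library$maps, fp("library_maps.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(result$library$similarity, fp("library_similarity.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  for (r in seq_along(result$seqs)) {
    write_label_sequence(result$seqs[[r]],
                         fp(sprintf("labels_run%03d.tsv", r)))
    write_frame_mask(result$masks[[r]],
                     fp(sprintf("mask_run%03d.tsv", r)))
  }
  write_transition_matrix(result$group_raw, fp("transitions_raw.tsv"))
  write_transition_matrix(result$group_norm, fp("transitions_normalized.tsv"))
  write_transition_matrix(result$group_resid,
                          fp("transitions_residualized.tsv"))
  write_transition_matrix(result$thresholded,
                          fp("transitions_thresholded.tsv"))
  utils::write.table(result$perm$p, fp("permutation_p.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(result$report)) {
    utils::write.table(result$report, fp("node_report.tsv"), sep = "\t",
                       row.names = FALSE, col.names = TRUE)
    el <- igraph::as_edgelist(result$graph)
    utils::write.table(
      data.frame(source = el[, 1], target = el[, 2],
                 weight = igraph::E(result$graph)$weight),
      fp("graph_edges.tsv"), sep = "\t", row.names = FALSE,
      col.names = TRUE)
  }
  log_lines <- c(
    sprintf("captrans pipeline log (%s)", format(Sys.time(), "%Y-%m-%d")),
    vapply(names(result$params), function(nm)
      sprintf("%s = %s", nm, paste(format(result$params[[nm]]),
                                   collapse = " ")), character(1)),
    sprintf("runs = %d", length(result$seqs)),
    sprintf("edges = %d", igraph::ecount(result$graph)),
    if (!is.null(result$reproducibility$split_half))
      sprintf("split_half = %.4f", result$reproducibility$split_half),
    sprintf("individual_mean = %.4f", result$reproducibility$individual$mean))
  writeLines(log_lines, fp("pipeline_log.txt"))
  invisible(out_dir)
}

#' Fraction of frames assigned a pattern label
#'
#' Among frames retained by the motion mask, the fraction whose best match
#' cleared the correlation threshold (label > 0).
#'
#' @param seqs List of `label_sequence` objects.
#' @param masks Optional list of `frame_mask` objects; when given, the
#'   denominator is restricted to kept frames.
#' @return Fraction in `[0, 1]`.
#' @export
matched_fraction <- function(seqs, masks = NULL) {
  tot <- 0; matched <- 0
  for (r in seq_along(seqs)) {
    labs <- label_vector(seqs[[r]])
    use <- if (is.null(masks)) rep(TRUE, length(labs)) else masks[[r]]$keep
    tot <- tot + sum(use)
    matched <- matched + sum(labs[use] > 0)
  }
  matched / tot
}
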