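#' Read and write delimited pipeline artifacts
#'
#' All pipeline artifacts are plain delimited text so results remain
#' portable and diffable: time series as `T x V` TSV, label sequences as
#' two columns (`label`, `best_r`), transition matrices as `K x K` TSV
#' with a comment header recording level and provenance, frame masks with
#' reason codes. 4D volumetric images (NIfTI) are supported through the
#' RNifti package: a `T x V` matrix is folded to an `X x Y x Z x T` grid
#' and back.
#'
#' @param ts,path,m,seq,mask,dim_xyz See the individual functions.
#' @name captrans_io
NULL

#' @rdname captrans_io
#' @param ts `T x V` matrix.
#' @param path Output file.
#' @export
write_timeseries_txt <- function(ts, path) {
  utils::write.table(as.matrix(ts), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname captrans_io
#' @export
read_timeseries_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @rdname captrans_io
#' @param dim_xyz Integer triple folding `V` voxels into a 3D grid
#'   (`prod(dim_xyz) >= V`; trailing cells zero-padded).
#' @export
write_nifti_run <- function(ts, path, dim_xyz = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support requires the RNifti package")
  ts <- as.matrix(ts)
  V <- ncol(ts); T_len <- nrow(ts)
  if (is.null(dim_xyz)) {
    side <- ceiling(V^(1 / 3))
    dim_xyz <- c(side, side, ceiling(V / side^2))
  }
  if (prod(dim_xyz) < V) stop("format error: grid smaller than V")
  arr <- array(0, dim = c(dim_xyz, T_len))
  for (t in seq_len(T_len)) {
    vol <- numeric(prod(dim_xyz)); vol[seq_len(V)] <- ts[t, ]
    arr[, , , t] <- vol
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname captrans_io
#' @param V Number of voxels to unfold from the grid (defaults to the
#'   whole grid).
#' @export
read_nifti_run <- function(path, V = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support requires the RNifti package")
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (length(d) != 4) stop("format error: expected a 4D image")
  if (is.null(V)) V <- prod(d[1:3])
  t(apply(arr, 4, function(v) as.vector(v)[seq_len(V)]))
}

#' @rdname captrans_io
#' @export
write_label_sequence <- function(seq, path) {
  df <- if (is.data.frame(seq)) seq[, c("label", "best_r")]
        else data.frame(label = as.integer(seq), best_r = NA_real_)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname captrans_io
#' @param K Number of patterns for the reconstructed `label_sequence`.
#' @export
read_label_sequence <- function(path, K = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  class(df) <- c("label_sequence", class(df))
  if (!is.null(K)) attr(df, "K") <- as.integer(K)
  df
}

#' @rdname captrans_io
#' @export
write_transition_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level: %s", attr(m, "level") %||% "raw_counts"), con)
  writeLines(sprintf("# provenance: %s", attr(m, "provenance") %||% ""), con)
  utils::write.table(unclass(m), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname captrans_io
#' @export
read_transition_matrix <- function(path) {
  hdr <- readLines(path, n = 2)
  level <- sub("^# level: ", "", hdr[1])
  prov <- sub("^# provenance: ", "", hdr[2])
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                      comment.char = "#"))
  dimnames(vals) <- NULL
  transition_matrix(vals, level = level, provenance = prov)
}

#' @rdname captrans_io
#' @export
write_frame_mask <- function(mask, path) {
  utils::write.table(mask, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname captrans_io
#' @export
read_frame_mask <- function(path) {
  mask <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  class(mask) <- c("frame_mask", class(mask))
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a
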