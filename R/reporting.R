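# Summaries of an accepted clustering: per-cluster density modes of the
# winning descriptors, cluster summary tables, and candidate exports.

#' Dominant mode of a density distribution
#'
#' Argmax of a Gaussian kernel density estimate evaluated on a 512-point
#' grid spanning `[min(x), max(x)]`. Bandwidth follows Scott's rule
#' (`stats::bw.nrd`) unless a numeric bandwidth is supplied; constant input
#' returns that constant directly.
#'
#' @param x Numeric values.
#' @param bw `"scott"`, `"silverman"`, or a positive numeric bandwidth.
#' @return The mode (scalar).
#' @export
density_mode <- function(x, bw = "scott") {
  x <- as.numeric(x)
  stopifnot(length(x) >= 1, all(is.finite(x)))
  if (length(unique(x)) == 1) return(x[1])
  bwv <- if (is.numeric(bw)) bw
    else if (identical(bw, "silverman")) bw.nrd0(x)
    else tryCatch(bw.nrd(x), error = function(e) bw.nrd0(x))
  if (!is.finite(bwv) || bwv <= 0) bwv <- bw.nrd0(x)
  if (!is.finite(bwv) || bwv <= 0) bwv <- diff(range(x)) / 10
  d <- density(x, bw = bwv, n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Per-cluster summaries of an accepted evaluation
#'
#' One summary per cluster: size, probable/improbable label, reference
#' count, and the dominant density mode of each descriptor in the winning
#' subset, computed over the cluster's rows.
#'
#' @param evaluation An accepted `"nos_subset_eval"`.
#' @param X The descriptor matrix the evaluation was run on.
#' @param ref Logical reference flags per row.
#' @return data.frame with one row per (cluster, descriptor): `cluster`,
#'   `label`, `size`, `ref_count`, `descriptor`, `mode`.
#' @export
summarize_clusters <- function(evaluation, X, ref) {
  stopifnot(inherits(evaluation, "nos_subset_eval"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(evaluation$labels), length(ref) == nrow(X))
  probable <- evaluation$probable_clusters
  rows <- list()
  for (k in seq_len(evaluation$n_clusters)) {
    in_k <- evaluation$labels == k
    for (j in evaluation$subset) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k,
        label = if (k %in% probable) "probable" else "improbable",
        size = sum(in_k),
        ref_count = sum(ref & in_k),
        descriptor = colnames(X)[j],
        mode = density_mode(X[in_k, j]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export probable and improbable candidates
#'
#' Writes two TSV files (`probable_candidates.tsv`,
#' `improbable_candidates.tsv`) containing the full candidate identifier
#' fields, all fifteen descriptors and the assigned cluster for every
#' non-reference pair. Verdict and descriptor tables must agree on their
#' candidate ids; any mismatch raises an error and nothing is written.
#'
#' @param verdicts data.frame from [label_candidates()].
#' @param vectors Descriptor data.frame carrying a `candidate_id` column.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
export_candidates <- function(verdicts, vectors, dir) {
  if (!all(verdicts$candidate_id %in% vectors$candidate_id))
    stop("export_candidates: verdict ids missing from descriptor table; nothing written")
  if (anyDuplicated(vectors$candidate_id))
    stop("export_candidates: duplicated candidate ids in descriptor table; nothing written")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- match(verdicts$candidate_id, vectors$candidate_id)
  full <- cbind(vectors[m, , drop = FALSE],
                cluster = verdicts$cluster, label = verdicts$label)
  rownames(full) <- NULL
  paths <- c(
    probable = file.path(dir, "probable_candidates.tsv"),
    improbable = file.path(dir, "improbable_candidates.tsv")
  )
  write_descriptor_tsv(full[full$label == "probable", , drop = FALSE],
                       paths[["probable"]])
  write_descriptor_tsv(full[full$label == "improbable", , drop = FALSE],
                       paths[["improbable"]])
  invisible(paths)
}
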