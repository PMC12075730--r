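# Exhaustive descriptor-subset search: for each subset of >= 3 descriptors,
# z-score the columns, embed into 2-3 dimensions with UMAP, cluster the
# embedding by mean-shift, score with the Silhouette, and accept the subset
# when the clustering is clean (2-3 clusters, Silhouette >= 0.5) and the
# verified reference linkages concentrate in the probable clusters.

#' Enumerate descriptor subsets
#'
#' Yields every subset of `{1, ..., n_descriptors}` with at least `min_size`
#' elements, ordered by (size, lexicographic). For the full pipeline
#' (n = 15, min = 3) this is sum_{i=3}^{15} C(15, i) = 32,647 subsets.
#'
#' @param n_descriptors Number of descriptors (columns).
#' @param min_size Smallest subset size considered.
#' @return list of integer vectors (sorted indices).
#' @export
#' @examples
#' length(enumerate_subsets(15, 3))  # sum(choose(15, 3:15)) = 32647
enumerate_subsets <- function(n_descriptors, min_size = 3) {
  stopifnot(n_descriptors >= 1, min_size >= 1)
  if (min_size > n_descriptors) return(list())
  out <- list()
  for (k in min_size:n_descriptors) {
    cmb <- combn(n_descriptors, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) as.integer(cmb[, j])))
  }
  out
}

# z-score standardization; zero-variance columns become all-zero so that
# mixed units (degrees, Angstrom, Angstrom^2, counts) weigh equally.
standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  Z <- sweep(X, 2, mu, "-")
  ok <- sdv > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sdv[ok], "/")
  Z[, !ok] <- 0
  Z
}

#' Embed a descriptor subset into 2-3 dimensions
#'
#' Standardizes the selected columns (z-score) and embeds them with UMAP.
#' The embedding dimension follows the subset size: 3 output dimensions for
#' subsets larger than 3 descriptors, 2 otherwise (never more than the
#' subset size). The embedding is deterministic for a fixed seed. When the
#' standardized submatrix has no row variation at all (all rows identical),
#' the degenerate all-zero embedding is returned directly, since a
#' stochastic-gradient layout would scatter exactly coincident points.
#'
#' @param X Numeric matrix or data.frame of descriptors (rows = pairs,
#'   including any injected reference rows).
#' @param subset Integer vector of column indices (or `NULL` for all).
#' @param dims Embedding dimension; `NULL` applies the size policy above.
#' @param cfg A [screening_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return n x dims coordinate matrix.
#' @export
embed_descriptors <- function(X, subset = NULL, dims = NULL,
                              cfg = screening_config(), seed = cfg$seed) {
  X <- as.matrix(X)
  if (is.null(subset)) subset <- seq_len(ncol(X))
  sub <- X[, subset, drop = FALSE]
  n <- nrow(sub)
  if (n < cfg$umap_n_neighbors + 1)
    stop("embed_descriptors: need at least n_neighbors + 1 = ",
         cfg$umap_n_neighbors + 1, " rows, got ", n)
  if (is.null(dims)) dims <- if (length(subset) > 3) 3L else 2L
  dims <- min(dims, length(subset))
  Z <- standardize_columns(sub)
  if (all(abs(Z) < 1e-12))
    return(matrix(0, n, dims))
  set.seed(seed)
  emb <- withCallingHandlers(
    uwot::umap(Z, n_components = dims, n_neighbors = cfg$umap_n_neighbors,
               min_dist = cfg$umap_min_dist, metric = "euclidean",
               n_epochs = cfg$umap_n_epochs, init = "spectral",
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE),
    warning = function(w) {
      if (grepl("connected component|initial|spectral|disconnect",
                conditionMessage(w), ignore.case = TRUE))
        invokeRestart("muffleWarning")
    })
  unname(emb)
}

# Bandwidth heuristic: for every point take the distance to its k-th
# nearest neighbour (k = floor(n * quantile)), and average.
estimate_bandwidth <- function(coords, quantile = 0.2) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  k <- max(1L, floor(n * quantile))
  kd <- apply(D, 1, function(row) sort(row)[k + 1L])  # +1 skips self (0)
  mean(kd)
}

#' Mean-shift clustering
#'
#' Mode-seeking clustering with a flat kernel: every point is shifted to
#' the mean of the points within `bandwidth` of its current position until
#' convergence; converged positions within one bandwidth of a stronger mode
#' are merged, and points are assigned to the nearest surviving mode.
#' Modes supported by fewer than `min_frac` of the points (outlier
#' satellites) are dissolved into the nearest surviving mode. Clusters are
#' numbered by descending size. When `bandwidth` is `NULL` it is estimated
#' by the nearest-neighbour quantile heuristic (`cfg$ms_quantile`).
#' Degenerate all-identical input yields one cluster.
#'
#' @param coords n x k coordinate matrix.
#' @param bandwidth Kernel radius, or `NULL` to estimate.
#' @param cfg A [screening_config()].
#' @param max_iter,tol Convergence controls.
#' @param min_frac Smallest fraction of points a mode may hold before it is
#'   dissolved. Default 0.05 (the smallest cluster of interest in this
#'   screen, the improbable cluster, is an order of magnitude larger).
#' @return list with `labels` (integer per row), `n_clusters`, `centers`
#'   and `bandwidth`.
#' @export
mean_shift <- function(coords, bandwidth = NULL, cfg = screening_config(),
                       max_iter = 300L, tol = 1e-4, min_frac = 0.05) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1)
  if (is.null(bandwidth)) bandwidth <- estimate_bandwidth(coords, cfg$ms_quantile)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    return(list(labels = rep(1L, n), n_clusters = 1L,
                centers = coords[1, , drop = FALSE], bandwidth = bandwidth))
  }
  bw2 <- bandwidth^2
  pos <- coords
  sq <- rowSums(coords^2)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(pos^2), sq, "+") - 2 * (pos %*% t(coords))
    w <- d2 <= bw2
    counts <- rowSums(w)
    newpos <- (w %*% coords) / counts
    shift <- sqrt(rowSums((newpos - pos)^2))
    pos <- newpos
    if (max(shift) < tol * bandwidth) break
  }
  # mode intensity = number of original points within one bandwidth
  d2 <- outer(rowSums(pos^2), sq, "+") - 2 * (pos %*% t(coords))
  intensity <- rowSums(d2 <= bw2)
  ord <- order(-intensity)
  centers <- matrix(numeric(0), 0, ncol(coords))
  for (i in ord) {
    if (nrow(centers) == 0) {
      centers <- pos[i, , drop = FALSE]
    } else {
      dc <- sqrt(rowSums((centers - matrix(pos[i, ], nrow(centers),
                                           ncol(coords), byrow = TRUE))^2))
      if (all(dc >= bandwidth)) centers <- rbind(centers, pos[i, , drop = FALSE])
    }
  }
  dcent <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
    2 * (coords %*% t(centers))
  labels <- max.col(-dcent, ties.method = "first")
  # dissolve outlier satellite modes into the nearest surviving mode
  min_size <- max(1L, ceiling(min_frac * n))
  repeat {
    sizes <- tabulate(labels, nbins = nrow(centers))
    weak <- which(sizes > 0 & sizes < min_size)
    if (length(weak) == 0 || length(weak) == sum(sizes > 0)) break
    strong <- which(sizes >= min_size)
    dstrong <- dcent[, strong, drop = FALSE]
    move <- labels %in% weak
    labels[move] <- strong[max.col(-dstrong[move, , drop = FALSE],
                                   ties.method = "first")]
  }
  # renumber by descending cluster size (ties: first-found order)
  sizes <- tabulate(labels, nbins = nrow(centers))
  keep <- which(sizes > 0)
  remap <- integer(nrow(centers))
  remap[keep[order(-sizes[keep])]] <- seq_along(keep)
  labels <- remap[labels]
  centers <- centers[keep[order(-sizes[keep])], , drop = FALSE]
  list(labels = labels, n_clusters = length(keep), centers = centers,
       bandwidth = bandwidth)
}

#' Mean Silhouette score of a clustering
#'
#' Mean over points of (b - a) / max(a, b) with Euclidean distances, where a
#' is the mean intra-cluster distance and b the smallest mean distance to
#' another cluster. Returns `NA_real_` (the undefined signal) when fewer
#' than two clusters are present.
#'
#' @param coords n x k coordinate matrix.
#' @param labels Integer cluster labels.
#' @return Scalar in `[-1, 1]`, or `NA_real_`.
#' @export
silhouette_score <- function(coords, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(labels), dist(coords))
  mean(sil[, "sil_width"])
}

# Acceptance rule for one evaluated subset. Probable clusters are those
# holding more reference linkages than the leak tolerance; a subset is
# accepted when the cluster count is in range, the Silhouette passes, an
# improbable (reference-poor) cluster exists — a feature space in which
# every cluster is reference-rich discriminates nothing — and at most
# ref_leak_tolerance references fall outside the probable clusters.
subset_verdict <- function(n_clusters, silhouette, ref_counts,
                           cfg = screening_config()) {
  probable <- which(ref_counts > cfg$ref_leak_tolerance)
  ref_leak <- sum(ref_counts) - sum(ref_counts[probable])
  if (n_clusters < 2)
    return(list(accepted = FALSE, reason = "single_cluster",
                probable = probable, ref_leak = ref_leak))
  if (n_clusters < cfg$min_clusters || n_clusters > cfg$max_clusters)
    return(list(accepted = FALSE, reason = "cluster_count",
                probable = probable, ref_leak = ref_leak))
  if (is.na(silhouette) || silhouette < cfg$min_silhouette)
    return(list(accepted = FALSE, reason = "silhouette",
                probable = probable, ref_leak = ref_leak))
  if (length(probable) == 0 || length(probable) == n_clusters)
    return(list(accepted = FALSE, reason = "no_improbable_cluster",
                probable = probable, ref_leak = ref_leak))
  if (ref_leak > cfg$ref_leak_tolerance)
    return(list(accepted = FALSE, reason = "ref_leak",
                probable = probable, ref_leak = ref_leak))
  list(accepted = TRUE, reason = NA_character_, probable = probable,
       ref_leak = ref_leak)
}

#' Evaluate one descriptor subset
#'
#' Embeds the subset, clusters the embedding, scores the Silhouette, tallies
#' reference linkages per cluster, and applies the acceptance rule: 2-3
#' clusters, Silhouette >= `cfg$min_silhouette`, and no more than
#' `cfg$ref_leak_tolerance` reference points outside the probable clusters.
#'
#' @param X Descriptor matrix (pairs + injected reference rows).
#' @param subset Integer column indices (size >= 3 in the full search).
#' @param ref Logical vector flagging reference rows of `X`.
#' @param cfg A [screening_config()].
#' @param seed Embedding seed; defaults to `cfg$seed`.
#' @return An object of class `"nos_subset_eval"`.
#' @export
evaluate_subset <- function(X, subset, ref, cfg = screening_config(),
                            seed = cfg$seed) {
  X <- as.matrix(X)
  stopifnot(length(ref) == nrow(X))
  emb <- embed_descriptors(X, subset, cfg = cfg, seed = seed)
  ms <- mean_shift(emb, cfg = cfg)
  sil <- silhouette_score(emb, ms$labels)
  sizes <- tabulate(ms$labels, nbins = ms$n_clusters)
  ref_counts <- vapply(seq_len(ms$n_clusters),
                       function(k) sum(ref & ms$labels == k), integer(1))
  v <- subset_verdict(ms$n_clusters, sil, ref_counts, cfg)
  structure(
    list(subset = as.integer(subset),
         descriptors = colnames(X)[subset],
         embedding = emb, labels = ms$labels,
         n_clusters = ms$n_clusters, cluster_sizes = sizes,
         silhouette = sil, ref_counts = ref_counts,
         probable_clusters = v$probable, ref_leak = v$ref_leak,
         accepted = v$accepted, reason = v$reason, seed = seed),
    class = "nos_subset_eval"
  )
}

#' @export
print.nos_subset_eval <- function(x, ...) {
  cat(sprintf("<nos_subset_eval> {%s} | %d clusters (%s) | silhouette %.3f | refs/cluster %s | %s\n",
              paste(x$descriptors, collapse = ", "), x$n_clusters,
              paste(x$cluster_sizes, collapse = "+"),
              ifelse(is.na(x$silhouette), NA, x$silhouette),
              paste(x$ref_counts, collapse = "/"),
              if (x$accepted) "ACCEPTED" else paste("rejected:", x$reason)))
  invisible(x)
}

#' Search a stream of descriptor subsets
#'
#' Evaluates every subset in `subsets` (default: all subsets of the given
#' sizes) with [evaluate_subset()], using the same seed for every subset so
#' that the outcome is independent of how the stream is partitioned.
#'
#' @param X Descriptor matrix (pairs + reference rows).
#' @param ref Logical reference-row flags.
#' @param cfg A [screening_config()].
#' @param sizes Subset sizes to enumerate when `subsets` is `NULL`.
#'   Defaults to `3:ncol(X)` (the full search).
#' @param subsets Optional explicit list of integer index vectors.
#' @param seed Embedding seed; defaults to `cfg$seed`.
#' @return list of class `"nos_search"` with `evaluations` (list of
#'   `"nos_subset_eval"`) and `summary` (one row per subset: size, cluster
#'   count, Silhouette, reference leak, accepted, rejection reason).
#' @export
search_descriptor_subsets <- function(X, ref, cfg = screening_config(),
                                      sizes = NULL, subsets = NULL,
                                      seed = cfg$seed) {
  X <- as.matrix(X)
  if (is.null(subsets)) {
    if (is.null(sizes)) sizes <- 3:ncol(X)
    sizes <- sort(unique(sizes))
    subsets <- list()
    for (k in sizes) {
      cmb <- combn(ncol(X), k)
      subsets <- c(subsets, lapply(seq_len(ncol(cmb)),
                                   function(j) as.integer(cmb[, j])))
    }
  }
  evals <- lapply(subsets, function(ss)
    evaluate_subset(X, ss, ref, cfg = cfg, seed = seed))
  summ <- data.frame(
    subset = vapply(evals, function(e) paste(e$subset, collapse = ","), character(1)),
    descriptors = vapply(evals, function(e) paste(e$descriptors, collapse = "+"), character(1)),
    size = vapply(evals, function(e) length(e$subset), integer(1)),
    n_clusters = vapply(evals, function(e) e$n_clusters, integer(1)),
    silhouette = vapply(evals, function(e) ifelse(is.na(e$silhouette), NA_real_, e$silhouette), numeric(1)),
    ref_leak = vapply(evals, function(e) as.integer(e$ref_leak), integer(1)),
    accepted = vapply(evals, function(e) e$accepted, logical(1)),
    reason = vapply(evals, function(e) ifelse(is.na(e$reason), "", e$reason), character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(evaluations = evals, summary = summ), class = "nos_search")
}

#' Rank accepted subsets and pick the minimal descriptor set
#'
#' Accepted subsets are ranked by (smallest size, fewest reference leaks,
#' highest Silhouette); the top subset is the minimal descriptor set. When
#' nothing is accepted, the result is empty and carries diagnostics (the
#' best Silhouette seen and the tally of rejection reasons).
#'
#' @param search A `"nos_search"` from [search_descriptor_subsets()].
#' @return list with `best` (a `"nos_subset_eval"` or `NULL`), `ranking`
#'   (data.frame of accepted subsets in rank order) and `diagnostics`.
#' @export
select_best <- function(search) {
  summ <- search$summary
  acc <- which(summ$accepted)
  diag <- list(
    n_evaluated = nrow(summ),
    n_accepted = length(acc),
    best_silhouette = if (all(is.na(summ$silhouette))) NA_real_
                      else max(summ$silhouette, na.rm = TRUE),
    rejection_reasons = table(summ$reason[summ$reason != ""])
  )
  if (length(acc) == 0)
    return(list(best = NULL, ranking = summ[0, ], diagnostics = diag))
  ord <- acc[order(summ$size[acc], summ$ref_leak[acc], -summ$silhouette[acc])]
  list(best = search$evaluations[[ord[1]]],
       ranking = cbind(rank = seq_along(ord), summ[ord, , drop = FALSE]),
       diagnostics = diag)
}

#' Probable / improbable verdicts under an accepted subset
#'
#' Clusters holding more reference linkages than the leak tolerance are
#' probable; every other cluster is improbable. All non-reference rows
#' inherit their cluster's label; reference rows are excluded from the
#' candidate list.
#'
#' @param evaluation An accepted `"nos_subset_eval"`.
#' @param ref Logical reference flags for the rows the evaluation was run on.
#' @param ids Optional character vector of candidate ids per row (defaults
#'   to row indices).
#' @return data.frame with `candidate_id`, `cluster`, `label`.
#' @export
label_candidates <- function(evaluation, ref, ids = NULL) {
  stopifnot(inherits(evaluation, "nos_subset_eval"))
  n <- length(evaluation$labels)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  stopifnot(length(ref) == n, length(ids) == n)
  probable <- evaluation$probable_clusters
  lab <- ifelse(evaluation$labels %in% probable, "probable", "improbable")
  out <- data.frame(candidate_id = ids[!ref],
                    cluster = evaluation$labels[!ref],
                    label = lab[!ref], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
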