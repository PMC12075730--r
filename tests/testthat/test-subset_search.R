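# Subset enumeration, embedding, mean-shift, silhouette and the
# acceptance/ranking logic.

test_that("subset enumeration counts match the binomial sums", {
  expect_length(enumerate_subsets(15, 3), sum(choose(15, 3:15)))
  expect_length(enumerate_subsets(3, 3), 1)
  expect_length(enumerate_subsets(4, 3), 5)
  expect_length(enumerate_subsets(5, 6), 0)
  for (n in c(4, 7, 11, 15)) {
    for (m in c(1, 3, n)) {
      expect_length(enumerate_subsets(n, m), sum(choose(n, m:n)))
    }
  }
  # each subset exactly once, ordered by (size, lexicographic)
  subs <- enumerate_subsets(5, 3)
  keys <- vapply(subs, paste, character(1), collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  sizes <- lengths(subs)
  expect_true(all(diff(sizes) >= 0))
})

test_that("embedding is deterministic, size-capped and guards degeneracy", {
  set.seed(5)
  X <- matrix(rnorm(60 * 6), 60, 6)
  cfg <- screening_config()
  e1 <- embed_descriptors(X, 1:4, cfg = cfg, seed = 9)
  e2 <- embed_descriptors(X, 1:4, cfg = cfg, seed = 9)
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 3)                      # |subset| > 3 -> 3 dims
  expect_equal(ncol(embed_descriptors(X, 1:3, cfg = cfg, seed = 9)), 2)

  # identical rows embed to coincident points
  Xd <- matrix(rep(c(3, 1, 4), each = 40), 40, 3)
  ed <- embed_descriptors(Xd, 1:3, cfg = cfg, seed = 9)
  expect_true(all(ed == 0))

  # fewer rows than the neighbourhood size is a parameter error
  expect_error(embed_descriptors(X[1:10, ], 1:3, cfg = cfg, seed = 9),
               "n_neighbors")
})

test_that("embedding keeps well-separated blobs separated", {
  b <- make_descriptor_blobs(n_rows = c(40, 40),
                             centers = rbind(c(0, 0, 0), c(20, 20, 20)),
                             informative = c(1, 2, 3), spread = 1, seed = 2)
  emb <- embed_descriptors(b$X, c(1, 2, 3), cfg = screening_config(), seed = 4)
  c1 <- colMeans(emb[b$blob == 1, , drop = FALSE])
  c2 <- colMeans(emb[b$blob == 2, , drop = FALSE])
  r1 <- sqrt(max(rowSums(sweep(emb[b$blob == 1, ], 2, c1)^2)))
  r2 <- sqrt(max(rowSums(sweep(emb[b$blob == 2, ], 2, c2)^2)))
  expect_gt(sqrt(sum((c1 - c2)^2)), r1 + r2)
})

test_that("mean-shift recovers planted partitions and sizes", {
  set.seed(11)
  mk_blob <- function(n, center) sweep(matrix(rnorm(n * 2, sd = 0.5), n, 2),
                                       2, center, "+")
  two <- rbind(mk_blob(60, c(0, 0)), mk_blob(40, c(10, 10)))
  ms2 <- mean_shift(two)
  expect_equal(ms2$n_clusters, 2)
  expect_equal(sort(tabulate(ms2$labels)), c(40, 60))
  truth <- rep(1:2, c(60, 40))
  agree <- max(mean(ms2$labels == truth), mean(ms2$labels == 3 - truth))
  expect_gte(agree, 0.99)

  one <- mk_blob(80, c(0, 0))
  expect_equal(mean_shift(one)$n_clusters, 1)

  three <- rbind(mk_blob(50, c(0, 0)), mk_blob(30, c(10, 10)),
                 mk_blob(20, c(-10, 10)))
  ms3 <- mean_shift(three)
  expect_equal(ms3$n_clusters, 3)
  expect_equal(sort(tabulate(ms3$labels)), c(20, 30, 50))
  # clusters numbered by descending size
  expect_equal(tabulate(ms3$labels), c(50, 30, 20))

  ident <- matrix(1, 30, 2)
  expect_equal(mean_shift(ident)$n_clusters, 1)
})

test_that("silhouette matches the O(n^2) textbook oracle", {
  set.seed(3)
  coords <- matrix(rnorm(200 * 3), 200, 3)
  labels <- sample(1:3, 200, replace = TRUE)
  expect_equal(silhouette_score(coords, labels),
               oracle_silhouette(coords, labels), tolerance = 1e-9)

  # two far-apart singletons approach a perfect score as separation grows
  prev <- -1
  for (sep in c(5, 50, 500)) {
    sc <- silhouette_score(rbind(c(0, 0), c(sep, 0), c(0.1, 0), c(sep - 0.1, 0)),
                           c(1, 2, 1, 2))
    expect_gt(sc, prev)
    prev <- sc
  }
  expect_gt(prev, 0.99)

  # random labels on a single blob stay near zero across seeds
  for (sd in 1:20) {
    set.seed(sd)
    blob <- matrix(rnorm(80 * 2), 80, 2)
    sc <- silhouette_score(blob, sample(1:2, 80, replace = TRUE))
    expect_lt(abs(sc), 0.2)
  }

  expect_true(is.na(silhouette_score(matrix(rnorm(20), 10, 2), rep(1, 10))))
})

test_that("the acceptance rule encodes the published gates", {
  cfg <- screening_config()
  # silhouette below 0.5 -> rejected for silhouette
  v <- nosscan:::subset_verdict(2, 0.45, c(70, 4), cfg)
  expect_false(v$accepted); expect_identical(v$reason, "silhouette")
  # more than three clusters -> rejected for cluster count
  v <- nosscan:::subset_verdict(4, 0.8, c(70, 2, 1, 1), cfg)
  expect_false(v$accepted); expect_identical(v$reason, "cluster_count")
  # one cluster -> undefined silhouette -> single-cluster rejection
  v <- nosscan:::subset_verdict(1, NA_real_, c(74), cfg)
  expect_false(v$accepted); expect_identical(v$reason, "single_cluster")
  # 73 refs in probable clusters, 1 leaked, tolerance 2 -> accepted
  v <- nosscan:::subset_verdict(2, 0.58, c(73, 1), cfg)
  expect_true(v$accepted); expect_equal(v$ref_leak, 1)
  # references spread over all clusters -> nothing improbable -> rejected
  v <- nosscan:::subset_verdict(2, 0.8, c(40, 34), cfg)
  expect_false(v$accepted); expect_identical(v$reason, "no_improbable_cluster")
  # too many references outside probable clusters -> rejected
  v <- nosscan:::subset_verdict(3, 0.8, c(70, 2, 2), cfg)
  expect_false(v$accepted); expect_identical(v$reason, "ref_leak")
})

test_that("candidate labels follow cluster reference counts", {
  ev <- structure(list(subset = 1:3, descriptors = letters[1:3],
                       labels = c(rep(1L, 40), rep(2L, 33), rep(3L, 10)),
                       n_clusters = 3L, cluster_sizes = c(40L, 33L, 10L),
                       silhouette = 0.7, ref_counts = c(40L, 33L, 1L),
                       probable_clusters = c(1L, 2L), ref_leak = 1L,
                       accepted = TRUE, reason = NA_character_, seed = 1L),
                  class = "nos_subset_eval")
  ref <- c(rep(TRUE, 74), rep(FALSE, 9))
  # refs: 40 in c1, 33 in c2, 1 in c3; non-refs fill the rest
  ev$labels <- c(rep(1L, 40), rep(2L, 33), 3L, rep(3L, 9))
  verdicts <- label_candidates(ev, ref)
  expect_equal(nrow(verdicts), 9)
  expect_true(all(verdicts$label[verdicts$cluster %in% c(1, 2)] == "probable"))
  expect_true(all(verdicts$label[verdicts$cluster == 3] == "improbable"))

  # all refs in one cluster: that cluster probable, the rest improbable
  ev2 <- ev
  ev2$ref_counts <- c(74L, 0L, 0L)
  ev2$probable_clusters <- 1L
  ev2$labels <- c(rep(1L, 74), rep(2L, 5), rep(3L, 4))
  v2 <- label_candidates(ev2, ref)
  expect_true(all(v2$label[v2$cluster == 1] == "probable"))
  expect_true(all(v2$label[v2$cluster != 1] == "improbable"))
})

test_that("ranking prefers small subsets, then leaks, then silhouette", {
  mk_eval <- function(subset, sil, leak, accepted = TRUE) {
    structure(list(subset = as.integer(subset),
                   descriptors = as.character(subset),
                   labels = c(1L, 2L), n_clusters = 2L,
                   cluster_sizes = c(1L, 1L), silhouette = sil,
                   ref_counts = c(5L, 0L), probable_clusters = 1L,
                   ref_leak = as.integer(leak), accepted = accepted,
                   reason = NA_character_, seed = 1L),
              class = "nos_subset_eval")
  }
  evals <- list(mk_eval(c(1, 2, 3), 0.55, 0), mk_eval(c(2, 3, 4), 0.61, 0),
                mk_eval(c(1, 2, 3, 4), 0.9, 0),
                mk_eval(c(9, 10, 11), 0.8, 2))
  summ <- data.frame(
    subset = vapply(evals, function(e) paste(e$subset, collapse = ","), character(1)),
    descriptors = "", size = vapply(evals, function(e) length(e$subset), integer(1)),
    n_clusters = 2L,
    silhouette = vapply(evals, function(e) e$silhouette, numeric(1)),
    ref_leak = vapply(evals, function(e) e$ref_leak, integer(1)),
    accepted = TRUE, reason = "", stringsAsFactors = FALSE)
  sel <- select_best(structure(list(evaluations = evals, summary = summ),
                               class = "nos_search"))
  expect_identical(sel$best$subset, c(2L, 3L, 4L))   # size 3, leak 0, sil 0.61
  expect_equal(sel$ranking$size[1], 3)
  expect_equal(sel$ranking$subset[4], "1,2,3,4")     # size-4 set ranks last

  # nothing accepted -> empty result with diagnostics
  summ$accepted <- FALSE; summ$reason <- "silhouette"
  sel0 <- select_best(structure(list(evaluations = evals, summary = summ),
                                class = "nos_search"))
  expect_null(sel0$best)
  expect_equal(sel0$diagnostics$n_accepted, 0)
  expect_true(is.finite(sel0$diagnostics$best_silhouette))
})

test_that("verdicts are invariant under positive column rescaling", {
  b <- make_descriptor_blobs(n_rows = c(30, 30),
                             centers = rbind(c(0, 0, 0), c(15, 15, 15)),
                             informative = c(1, 2, 3), spread = 1,
                             n_reference = 20, ref_blob = 1, seed = 6)
  cfg <- screening_config()
  ev1 <- evaluate_subset(b$X, c(1, 2, 3), b$ref, cfg, seed = 3)
  Xs <- b$X
  Xs[, 1] <- Xs[, 1] * 1000
  Xs[, 3] <- Xs[, 3] * 0.01
  ev2 <- evaluate_subset(Xs, c(1, 2, 3), b$ref, cfg, seed = 3)
  expect_identical(ev1$labels, ev2$labels)
  expect_identical(ev1$accepted, ev2$accepted)
  expect_equal(ev1$silhouette, ev2$silhouette, tolerance = 1e-8)
})

test_that("rows identical to reference vectors share the reference cluster", {
  b <- make_descriptor_blobs(n_rows = c(30, 30),
                             centers = rbind(c(0, 0, 0), c(15, 15, 15)),
                             informative = c(1, 2, 3), spread = 1,
                             n_reference = 10, ref_blob = 1, seed = 12)
  # duplicate three reference rows as unlabeled data rows
  dup <- b$X[b$ref, ][1:3, , drop = FALSE]
  X <- rbind(b$X, dup)
  ref <- c(b$ref, rep(FALSE, 3))
  ev <- evaluate_subset(X, c(1, 2, 3), ref, screening_config(), seed = 5)
  dup_idx <- nrow(b$X) + 1:3
  src_idx <- which(b$ref)[1:3]
  expect_identical(ev$labels[dup_idx], ev$labels[src_idx])
})

test_that("search outcome is independent of stream partitioning", {
  b <- make_descriptor_blobs(n_rows = c(25, 25),
                             centers = rbind(c(0, 0, 0), c(15, 15, 15)),
                             informative = c(1, 2, 3), spread = 1,
                             n_reference = 12, ref_blob = 1, seed = 8)
  cfg <- screening_config()
  stream <- list(c(1L, 2L, 3L), c(4L, 5L, 6L), c(7L, 8L, 9L))
  full <- search_descriptor_subsets(b$X, b$ref, cfg, subsets = stream, seed = 2)
  parts <- lapply(stream, function(ss)
    search_descriptor_subsets(b$X, b$ref, cfg, subsets = list(ss), seed = 2))
  merged <- do.call(rbind, lapply(parts, function(p) p$summary))
  rownames(merged) <- NULL
  expect_equal(full$summary, merged)
})
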