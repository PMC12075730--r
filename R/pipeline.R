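# End-to-end driver: screen a corpus directory, extract descriptors,
# inject reference vectors, search descriptor subsets, label candidates.

#' Screen a corpus directory
#'
#' Walks a directory laid out as `<id>/structure.cif`, `<id>/bdb.pdb`,
#' `<id>/validation.xml` (the layout [make_corpus()] writes and the layout
#' used for locally mirrored PDB-REDO/BDB entries), applies the entry-level
#' metadata filter, enumerates S-N contacts in the default target classes,
#' and applies the per-pair quality filters. Every rejection — entry level
#' (`method`, `resolution`, `missing_resolution`), contact level
#' (`no_contact`) or pair level (`occupancy`, `missing_rsrz`, `rsrz`,
#' `bdb_missing`) — is logged with the first failed criterion.
#'
#' @param dir Corpus directory.
#' @param cfg A [screening_config()].
#' @return list of class `"nos_screen"`: `retained` (quality-filtered
#'   contact table with close-contact flags), `log` (data.frame `pdb_id`,
#'   `stage`, `reason`, one row per rejection event), and `entries` (named
#'   list of per-entry `structure`, `bdb`, `validation` objects for the
#'   retained entries).
#' @export
screen_corpus <- function(dir, cfg = screening_config()) {
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  ids <- ids[file.exists(file.path(dir, ids, "structure.cif"))]
  retained <- list(); log <- list(); entries <- list()
  for (id in ids) {
    edir <- file.path(dir, id)
    s <- read_structure(file.path(edir, "structure.cif"), format = "mmcif")
    ef <- passes_entry_filters(s, cfg)
    if (!ef$pass) {
      log[[length(log) + 1L]] <- data.frame(pdb_id = s$pdb_id, stage = "entry",
                                            reason = ef$reason,
                                            stringsAsFactors = FALSE)
      next
    }
    bdb <- read_bdb_bfactors(file.path(edir, "bdb.pdb"))
    val <- read_validation_report(file.path(edir, "validation.xml"))
    pairs <- select_target_classes(find_sn_contacts(s, cfg), cfg)
    if (nrow(pairs) == 0) {
      log[[length(log) + 1L]] <- data.frame(pdb_id = s$pdb_id, stage = "contact",
                                            reason = "no_contact",
                                            stringsAsFactors = FALSE)
      next
    }
    qf <- apply_quality_filters(pairs, s, bdb, val, cfg)
    if (nrow(qf$rejected) > 0) {
      log[[length(log) + 1L]] <- data.frame(pdb_id = qf$rejected$pdb_id,
                                            stage = "pair",
                                            reason = qf$rejected$reason,
                                            stringsAsFactors = FALSE)
    }
    if (nrow(qf$retained) > 0) {
      retained[[length(retained) + 1L]] <-
        annotate_close_contacts(qf$retained, val)
      entries[[s$pdb_id]] <- list(structure = s, bdb = bdb, validation = val)
    }
  }
  ret <- if (length(retained) > 0) do.call(rbind, retained) else NULL
  lg <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(pdb_id = character(), stage = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(lg) <- NULL
  structure(list(retained = ret, log = lg, entries = entries),
            class = "nos_screen")
}

#' Run the full NOS-candidate pipeline on a corpus
#'
#' Screen -> descriptors -> reference injection -> subset search ->
#' verdicts. The reference descriptor vectors (computed on verified
#' linkages, or synthetic stand-ins from [make_reference_vectors()]) are
#' appended as rows to the descriptor matrix before embedding, exactly as
#' the subset search expects.
#'
#' @param dir Corpus directory (see [screen_corpus()]).
#' @param reference data.frame with `candidate_id` and the 15 descriptor
#'   columns of [nos_descriptor_names()].
#' @param cfg A [screening_config()].
#' @param sizes,subsets Subset stream passed to
#'   [search_descriptor_subsets()]; the default searches all size-3
#'   subsets, the desk-scale setting (the full stream is `sizes = 3:15`).
#' @param seed Embedding seed; defaults to `cfg$seed`.
#' @param out_dir Optional directory for candidate TSV exports.
#' @return list of class `"nos_pipeline"` with elements `screen`,
#'   `descriptors`, `search`, `selection`, `verdicts`, `summaries`,
#'   `export_paths` (the last three `NULL` when no subset is accepted).
#' @export
run_nos_pipeline <- function(dir, reference, cfg = screening_config(),
                             sizes = 3, subsets = NULL, seed = cfg$seed,
                             out_dir = NULL) {
  sc <- screen_corpus(dir, cfg)
  if (is.null(sc$retained) || nrow(sc$retained) == 0)
    stop("run_nos_pipeline: no contact pairs survived screening")
  desc <- list()
  for (id in names(sc$entries)) {
    rows <- sc$retained[sc$retained$pdb_id == id, , drop = FALSE]
    desc[[id]] <- compute_descriptors(sc$entries[[id]]$structure, rows, cfg)
  }
  desc <- do.call(rbind, desc)
  rownames(desc) <- NULL
  nms <- nos_descriptor_names()
  stopifnot(all(nms %in% names(reference)))
  X <- rbind(as.matrix(desc[, nms, drop = FALSE]),
             as.matrix(reference[, nms, drop = FALSE]))
  ref <- c(rep(FALSE, nrow(desc)), rep(TRUE, nrow(reference)))
  ids <- c(desc$candidate_id, reference$candidate_id)
  search <- search_descriptor_subsets(X, ref, cfg, sizes = sizes,
                                      subsets = subsets, seed = seed)
  sel <- select_best(search)
  verdicts <- NULL; summaries <- NULL; paths <- NULL
  if (!is.null(sel$best)) {
    verdicts <- label_candidates(sel$best, ref, ids)
    summaries <- summarize_clusters(sel$best, X, ref)
    if (!is.null(out_dir))
      paths <- export_candidates(verdicts, desc, out_dir)
  }
  structure(list(screen = sc, descriptors = desc, search = search,
                 selection = sel, verdicts = verdicts, summaries = summaries,
                 export_paths = paths),
            class = "nos_pipeline")
}
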