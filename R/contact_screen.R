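# Enumeration of candidate S-N contact pairs and the per-pair quality
# filters (occupancy, RSRZ, BDB availability), plus pair-class bookkeeping.

# Sulfur donors and nitrogen acceptors considered by the screen.
SULFUR_ATOMS <- c(CYS = "SG", MET = "SD")
SIDECHAIN_N <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2"
)

pair_class_string <- function(resid_s, resid_n, n_class, atom_n) {
  paste(resid_s, resid_n, n_class, atom_n, sep = ".")
}

#' Enumerate sulfur-nitrogen contact pairs
#'
#' Candidate sulfur donors are the side-chain sulfurs of cysteine (SG) and
#' methionine (SD); nitrogen acceptors are the backbone N of every standard
#' residue plus the side-chain nitrogens of Lys, Arg, His, Trp, Asn and Gln.
#' A pair is returned when dist(S,N) <= `cfg$max_sn_dist` (inclusive, with
#' the configured numerical guard); pairs within a single residue are
#' excluded. Every surviving pair appears exactly once.
#'
#' @param s A `"nos_structure"`.
#' @param cfg A [screening_config()].
#' @return data.frame of contact pairs (class `"nos_contacts"`): provenance
#'   columns for both atoms, `dist_sn`, nitrogen class (`backbone` /
#'   `sidechain`) and `pair_class`.
#' @export
find_sn_contacts <- function(s, cfg = screening_config()) {
  stopifnot(inherits(s, "nos_structure"))
  at <- s$atoms
  is_s <- at$resid %in% names(SULFUR_ATOMS) &
    at$atom == unname(SULFUR_ATOMS[at$resid])
  is_bb_n <- at$resid %in% STANDARD_RESIDUES & at$atom == "N"
  is_sc_n <- rep(FALSE, nrow(at))
  for (res in names(SIDECHAIN_N)) {
    is_sc_n <- is_sc_n | (at$resid == res & at$atom %in% SIDECHAIN_N[[res]])
  }
  si <- which(is_s)
  ni <- which(is_bb_n | is_sc_n)
  empty <- data.frame(
    pdb_id = character(), chain_s = character(), resid_s = character(),
    resno_s = integer(), insert_s = character(), atom_s = character(),
    chain_n = character(), resid_n = character(), resno_n = integer(),
    insert_n = character(), atom_n = character(), n_class = character(),
    dist_sn = numeric(), pair_class = character(), stringsAsFactors = FALSE
  )
  if (length(si) == 0 || length(ni) == 0) {
    class(empty) <- c("nos_contacts", "data.frame")
    return(empty)
  }
  sxyz <- as.matrix(at[si, c("x", "y", "z")])
  nxyz <- as.matrix(at[ni, c("x", "y", "z")])
  d2 <- outer(rowSums(sxyz^2), rowSums(nxyz^2), "+") - 2 * (sxyz %*% t(nxyz))
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  keep <- which(d <= cfg$max_sn_dist + cfg$dist_epsilon, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    class(empty) <- c("nos_contacts", "data.frame")
    return(empty)
  }
  i_s <- si[keep[, 1]]
  i_n <- ni[keep[, 2]]
  same_res <- residue_key(at[i_s, ]) == residue_key(at[i_n, ])
  i_s <- i_s[!same_res]; i_n <- i_n[!same_res]
  dd <- d[keep][!same_res]
  if (length(i_s) == 0) {
    class(empty) <- c("nos_contacts", "data.frame")
    return(empty)
  }
  n_class <- ifelse(at$atom[i_n] == "N", "backbone", "sidechain")
  out <- data.frame(
    pdb_id = s$pdb_id,
    chain_s = at$chain[i_s], resid_s = at$resid[i_s],
    resno_s = at$resno[i_s], insert_s = at$insert[i_s], atom_s = at$atom[i_s],
    chain_n = at$chain[i_n], resid_n = at$resid[i_n],
    resno_n = at$resno[i_n], insert_n = at$insert[i_n], atom_n = at$atom[i_n],
    n_class = n_class,
    dist_sn = dd,
    pair_class = pair_class_string(at$resid[i_s], at$resid[i_n], n_class,
                                   at$atom[i_n]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chain_s, out$resno_s, out$atom_s,
                   out$chain_n, out$resno_n, out$atom_n), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nos_contacts", "data.frame")
  out
}

#' Restrict contacts to the default target classes
#'
#' Drops methionine sulfur donors and the Cys-Cys backbone and His-Cys
#' classes unless the configuration keeps them: Cys-Cys backbone proximity
#' is usually a disulfide bridge, and histidine contacts are dominated by
#' metal coordination, so neither is a clean NOS candidate class.
#'
#' @param pairs A `"nos_contacts"` data.frame.
#' @param cfg A [screening_config()].
#' @return The filtered contact table.
#' @export
select_target_classes <- function(pairs, cfg = screening_config()) {
  keep <- rep(TRUE, nrow(pairs))
  if (!cfg$include_met) keep <- keep & pairs$resid_s != "MET"
  if (!cfg$include_excluded_classes) {
    keep <- keep & !(pairs$resid_s == "CYS" & pairs$resid_n == "CYS" &
                       pairs$n_class == "backbone")
    keep <- keep & !(pairs$resid_n == "HIS")
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply per-pair quality filters
#'
#' A pair is retained when (i) both target atoms have occupancy strictly
#' above `cfg$min_occupancy`, (ii) both partner residues have RSRZ strictly
#' below `cfg$max_rsrz` in the validation report, and (iii) both target
#' atoms carry a B-factor in the BDB table. The rejection log records the
#' first failed criterion per dropped pair, in the documented order
#' occupancy, RSRZ (`missing_rsrz` when the residue is absent from the
#' report), BDB availability. The retained set is independent of this order
#' because the criteria are independent.
#'
#' @param pairs A `"nos_contacts"` data.frame.
#' @param s The `"nos_structure"` the pairs came from.
#' @param bdb A `"bdb_table"` for the same entry.
#' @param val A `"nos_validation"` for the same entry.
#' @param cfg A [screening_config()].
#' @return list with `retained` (contact table plus occupancy/RSRZ/B-factor
#'   columns) and `rejected` (contact table plus `reason`).
#' @export
apply_quality_filters <- function(pairs, s, bdb, val, cfg = screening_config()) {
  at <- s$atoms
  akey <- atom_key(at)
  idx_s <- match(paste(pairs$chain_s, pairs$resno_s, pairs$insert_s,
                       pairs$atom_s, sep = "|"), akey)
  idx_n <- match(paste(pairs$chain_n, pairs$resno_n, pairs$insert_n,
                       pairs$atom_n, sep = "|"), akey)
  occ_s <- at$o[idx_s]
  occ_n <- at$o[idx_n]
  bfac_pdb_s <- at$b[idx_s]
  bfac_pdb_n <- at$b[idx_n]
  rsrz_s <- rsrz_lookup(val, pairs$chain_s, pairs$resno_s, pairs$insert_s)
  rsrz_n <- rsrz_lookup(val, pairs$chain_n, pairs$resno_n, pairs$insert_n)
  bdb_s <- bfactor_lookup(bdb, pairs$chain_s, pairs$resno_s, pairs$insert_s,
                          pairs$atom_s)
  bdb_n <- bfactor_lookup(bdb, pairs$chain_n, pairs$resno_n, pairs$insert_n,
                          pairs$atom_n)

  reason <- rep(NA_character_, nrow(pairs))
  fail_occ <- !(occ_s > cfg$min_occupancy) | !(occ_n > cfg$min_occupancy)
  reason[is.na(reason) & fail_occ] <- "occupancy"
  miss_rsrz <- is.na(rsrz_s) | is.na(rsrz_n)
  reason[is.na(reason) & miss_rsrz] <- "missing_rsrz"
  fail_rsrz <- !miss_rsrz & (!(rsrz_s < cfg$max_rsrz) | !(rsrz_n < cfg$max_rsrz))
  reason[is.na(reason) & fail_rsrz] <- "rsrz"
  fail_bdb <- is.na(bdb_s) | is.na(bdb_n)
  reason[is.na(reason) & fail_bdb] <- "bdb_missing"

  aug <- cbind(pairs,
               data.frame(occ_s = occ_s, occ_n = occ_n,
                          bfac_pdb_s = bfac_pdb_s, bfac_pdb_n = bfac_pdb_n,
                          bfac_bdb_s = bdb_s, bfac_bdb_n = bdb_n,
                          rsrz_s = rsrz_s, rsrz_n = rsrz_n,
                          stringsAsFactors = FALSE))
  retained <- aug[is.na(reason), , drop = FALSE]
  rejected <- cbind(pairs[!is.na(reason), , drop = FALSE],
                    data.frame(reason = reason[!is.na(reason)],
                               stringsAsFactors = FALSE))
  rownames(retained) <- NULL
  rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Tabulate contact-pair class frequencies
#'
#' Counts contact pairs per pair class within one nitrogen grouping
#' (backbone or side-chain), sorted by descending count with alphabetical
#' tie-breaking. Class abundance is what picks the candidate classes worth
#' screening (Gly-Cys for backbone nitrogens, Arg-Cys for side chains).
#'
#' @param pairs A `"nos_contacts"` data.frame (possibly from several
#'   structures).
#' @param grouping `"backbone"` or `"sidechain"`.
#' @return data.frame with `pair_class` and `count`.
#' @export
tabulate_pair_frequencies <- function(pairs, grouping = c("backbone", "sidechain")) {
  grouping <- match.arg(grouping)
  sub <- pairs[pairs$n_class == grouping, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(pair_class = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(sub$pair_class)
  out <- data.frame(pair_class = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pair_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag pairs listed as close contacts in the validation report
#'
#' Adds a logical `flagged` column: `TRUE` when the (S, N) atom pair appears
#' in the report's close-contact list (matched unordered). Around 45% of
#' previously verified Lys-NOS-Cys linkages are flagged this way, so the
#' flag is informative, not disqualifying.
#'
#' @param pairs A `"nos_contacts"` data.frame.
#' @param val A `"nos_validation"`.
#' @return `pairs` with an extra `flagged` column.
#' @export
annotate_close_contacts <- function(pairs, val) {
  cc <- val$close_contacts
  if (nrow(pairs) == 0) {
    pairs$flagged <- logical(0)
    return(pairs)
  }
  k_s <- paste(pairs$chain_s, pairs$resno_s, pairs$insert_s, pairs$atom_s, sep = "|")
  k_n <- paste(pairs$chain_n, pairs$resno_n, pairs$insert_n, pairs$atom_n, sep = "|")
  pk <- paste(pmin(k_s, k_n), pmax(k_s, k_n))
  if (nrow(cc) == 0) {
    pairs$flagged <- rep(FALSE, nrow(pairs))
    return(pairs)
  }
  c1 <- paste(cc$chain1, cc$resno1, cc$insert1, cc$atom1, sep = "|")
  c2 <- paste(cc$chain2, cc$resno2, cc$insert2, cc$atom2, sep = "|")
  ck <- paste(pmin(c1, c2), pmax(c1, c2))
  pairs$flagged <- pk %in% ck
  pairs
}
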