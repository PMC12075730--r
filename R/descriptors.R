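# The fifteen per-pair descriptors: contact geometry (2 angles, 1 torsion,
# 2 distances), deposited and BDB B-factors of both target atoms, residue
# packing counts around both C-alphas, and Shrake-Rupley solvent
# accessibilities of both atoms and both residues.

#' Canonical descriptor names and order
#'
#' The fixed column order of every descriptor matrix produced or consumed by
#' the package. Suffix `_s` refers to the sulfur side of the contact, `_n`
#' to the nitrogen side.
#'
#' @return Character vector of the 15 descriptor names.
#' @export
nos_descriptor_names <- function() {
  c("angle_csn", "angle_cns", "torsion_cs_nc", "dist_cn", "dist_sn",
    "bfac_pdb_n", "bfac_pdb_s", "bfac_bdb_n", "bfac_bdb_s",
    "ngb_n", "ngb_s",
    "sasa_atom_n", "sasa_atom_s", "sasa_res_n", "sasa_res_s")
}

# id columns carried alongside the descriptors
nos_id_columns <- function() {
  c("candidate_id", "pdb_id", "chain_s", "resid_s", "resno_s", "insert_s",
    "atom_s", "chain_n", "resid_n", "resno_n", "insert_n", "atom_n")
}

vnorm <- function(v) sqrt(sum(v^2))

angle_deg <- function(a, b, c) {
  # angle at b between a and c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

torsion_deg <- function(p1, p2, p3, p4) {
  # signed dihedral over p1-p2-p3-p4 (right-hand rule about p2->p3),
  # range (-180, 180]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2u <- b2 / vnorm(b2)
  m1 <- c(b2u[2] * n1[3] - b2u[3] * n1[2],
          b2u[3] * n1[1] - b2u[1] * n1[3],
          b2u[1] * n1[2] - b2u[2] * n1[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Order residues as they appear in the atom table; used to resolve the
# "preceding residue" of a backbone nitrogen.
residue_order <- function(at) {
  rk <- residue_key(at)
  unique(rk)
}

#' Closest covalently bound carbon
#'
#' Resolves the carbon used as the outer atom of the contact geometry: the
#' carbon within covalent range (`cfg$covalent_max`, default 1.9 Angstrom)
#' of the target atom that minimizes the distance. Candidates are restricted
#' to carbons of the same residue plus, for a backbone nitrogen, the
#' preceding residue's carbonyl carbon. Returns `NA` (a descriptor-failure
#' signal) when no carbon lies within covalent range.
#'
#' @param s A `"nos_structure"`.
#' @param chain,resno,insert,atom Key of the target S or N atom.
#' @param cfg A [screening_config()].
#' @return Integer row index into `s$atoms`, or `NA_integer_`.
#' @export
nearest_bonded_carbon <- function(s, chain, resno, insert = "", atom,
                                  cfg = screening_config()) {
  at <- s$atoms
  akey <- atom_key(at)
  ti <- match(paste(chain, resno, insert, atom, sep = "|"), akey)
  if (is.na(ti)) stop("nearest_bonded_carbon: target atom not found")
  rk <- residue_key(at)
  cand <- which(rk == rk[ti] & at$element == "C")
  if (at$atom[ti] == "N") {
    ord <- residue_order(at)
    pos <- match(rk[ti], ord)
    if (pos > 1) {
      prev <- ord[pos - 1]
      prev_chain <- strsplit(prev, "|", fixed = TRUE)[[1]][1]
      if (identical(prev_chain, chain)) {
        cand <- c(cand, which(rk == prev & at$atom == "C"))
      }
    }
  }
  if (length(cand) == 0) return(NA_integer_)
  tx <- as.numeric(at[ti, c("x", "y", "z")])
  d <- apply(as.matrix(at[cand, c("x", "y", "z")]), 1,
             function(p) vnorm(p - tx))
  ok <- d <= cfg$covalent_max + cfg$dist_epsilon
  if (!any(ok)) return(NA_integer_)
  cand[ok][which.min(d[ok])]
}

#' Contact geometry for one pair
#'
#' Computes the five geometric descriptors of an S-N contact: the angle at
#' the sulfur between its bonded carbon and the nitrogen (angle_csn), the
#' angle at the nitrogen between its bonded carbon and the sulfur
#' (angle_cns), the signed torsion over C_S-S-N-C_N (right-hand rule, range
#' (-180, 180]), the distance from C_S to N (dist_cn) and the S-N distance.
#'
#' @param s A `"nos_structure"`.
#' @param pair One row of a `"nos_contacts"` data.frame.
#' @param cfg A [screening_config()].
#' @return Named numeric vector of the five values, or `NULL` when a bonded
#'   carbon cannot be resolved.
#' @export
compute_geometry <- function(s, pair, cfg = screening_config()) {
  at <- s$atoms
  akey <- atom_key(at)
  i_s <- match(paste(pair$chain_s, pair$resno_s, pair$insert_s, pair$atom_s,
                     sep = "|"), akey)
  i_n <- match(paste(pair$chain_n, pair$resno_n, pair$insert_n, pair$atom_n,
                     sep = "|"), akey)
  i_cs <- nearest_bonded_carbon(s, pair$chain_s, pair$resno_s, pair$insert_s,
                                pair$atom_s, cfg)
  i_cn <- nearest_bonded_carbon(s, pair$chain_n, pair$resno_n, pair$insert_n,
                                pair$atom_n, cfg)
  if (is.na(i_cs) || is.na(i_cn)) return(NULL)
  S <- as.numeric(at[i_s, c("x", "y", "z")])
  N <- as.numeric(at[i_n, c("x", "y", "z")])
  CS <- as.numeric(at[i_cs, c("x", "y", "z")])
  CN <- as.numeric(at[i_cn, c("x", "y", "z")])
  c(angle_csn = angle_deg(CS, S, N),
    angle_cns = angle_deg(CN, N, S),
    torsion_cs_nc = torsion_deg(CS, S, N, CN),
    dist_cn = vnorm(N - CS),
    dist_sn = vnorm(N - S))
}

# Deterministic golden-section spiral on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA by sampling `cfg$sasa_points` deterministic
#' golden-spiral points on each atom's solvent-expanded sphere (van der
#' Waals radius + probe) and counting points not buried inside any other
#' expanded sphere. Per-residue SASA is the exact sum of its atoms' values.
#' Waters and hydrogens are excluded. Van der Waals radii: C 1.70, N 1.55,
#' O 1.52, S 1.80 Angstrom; other elements fall back, with a warning, to
#' `cfg$sasa_default_radius`.
#'
#' @param s A `"nos_structure"`.
#' @param cfg A [screening_config()].
#' @return list with `atom` (data.frame `chain`, `resno`, `insert`, `atom`,
#'   `sasa`) and `residue` (data.frame `chain`, `resno`, `insert`, `sasa`).
#' @export
compute_sasa <- function(s, cfg = screening_config()) {
  at <- s$atoms
  keep <- !(at$resid %in% cfg$water_residues) & !(at$element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  n <- nrow(at)
  if (n == 0) stop("compute_sasa: no atoms after water/hydrogen exclusion")
  radii <- unname(VDW_RADII[at$element])
  if (anyNA(radii)) {
    unk <- unique(at$element[is.na(radii)])
    warning("compute_sasa: unknown element(s) ", paste(unk, collapse = ", "),
            "; using default radius ", cfg$sasa_default_radius, " A")
    radii[is.na(radii)] <- cfg$sasa_default_radius
  }
  probe <- cfg$sasa_probe_radius
  R <- radii + probe
  pts <- sphere_points(cfg$sasa_points)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  sasa <- numeric(n)
  # neighbour prefilter: atoms j can bury points of i only if
  # dist(i, j) < R_i + R_j
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * (xyz %*% t(xyz))
  d2[d2 < 0] <- 0
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nbr) == 0) {
      sasa[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in nbr) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & (dj2 > R[j]^2)
    }
    sasa[i] <- 4 * pi * R[i]^2 * sum(free) / nrow(p)
  }
  atom_tab <- data.frame(chain = at$chain, resno = at$resno,
                         insert = at$insert, atom = at$atom, sasa = sasa,
                         stringsAsFactors = FALSE)
  rk <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_sum <- tapply(sasa, rk, sum)
  first <- !duplicated(rk)
  res_tab <- data.frame(chain = at$chain[first], resno = at$resno[first],
                        insert = at$insert[first],
                        sasa = as.numeric(res_sum[rk[first]]),
                        stringsAsFactors = FALSE)
  rownames(res_tab) <- NULL
  list(atom = atom_tab, residue = res_tab)
}

#' Count neighbouring residues around a C-alpha
#'
#' Number of distinct other residues having at least one (non-hydrogen,
#' non-water) atom within `radius` (inclusive) of the C-alpha of the stated
#' residue. Returns `NA` (descriptor failure) when the residue has no
#' C-alpha.
#'
#' @param s A `"nos_structure"`.
#' @param chain,resno,insert Residue key.
#' @param radius Radius in Angstrom; defaults to the configured 4.0.
#' @param cfg A [screening_config()].
#' @return Integer count, or `NA_integer_`.
#' @export
count_neighbors <- function(s, chain, resno, insert = "",
                            radius = NULL, cfg = screening_config()) {
  if (is.null(radius)) radius <- cfg$neighbor_radius
  at <- s$atoms
  rk3 <- paste(at$chain, at$resno, at$insert, sep = "|")
  self <- paste(chain, resno, insert, sep = "|")
  ca <- which(rk3 == self & at$atom == "CA")
  if (length(ca) == 0) return(NA_integer_)
  ca_xyz <- as.numeric(at[ca[1], c("x", "y", "z")])
  others <- at[rk3 != self &
                 !(at$resid %in% cfg$water_residues) &
                 !(at$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(others) == 0) return(0L)
  d <- sqrt((others$x - ca_xyz[1])^2 + (others$y - ca_xyz[2])^2 +
              (others$z - ca_xyz[3])^2)
  within <- d <= radius + cfg$dist_epsilon
  length(unique(paste(others$chain, others$resno, others$insert,
                      sep = "|")[within]))
}

#' Compute the fifteen descriptors for retained contact pairs
#'
#' Runs geometry, B-factor, packing and SASA extraction for every pair that
#' survived [apply_quality_filters()] and assembles one descriptor row per
#' pair, in the canonical column order of [nos_descriptor_names()], together
#' with the candidate identifier fields (atom names, residue names, residue
#' numbers, chains, entry id). Pairs for which any component is unavailable
#' (no bonded carbon, missing C-alpha, missing B-factor) are excluded and
#' logged with a reason.
#'
#' @param s A `"nos_structure"`.
#' @param retained Retained contact table from [apply_quality_filters()]
#'   (must carry the occupancy/B-factor columns that stage adds).
#' @param cfg A [screening_config()].
#' @return data.frame with the id columns and 15 descriptor columns;
#'   attribute `"excluded"` is a data.frame of dropped pairs with reasons.
#' @export
compute_descriptors <- function(s, retained, cfg = screening_config()) {
  sasa <- compute_sasa(s, cfg)
  sasa_atom_key <- paste(sasa$atom$chain, sasa$atom$resno, sasa$atom$insert,
                         sasa$atom$atom, sep = "|")
  sasa_res_key <- paste(sasa$residue$chain, sasa$residue$resno,
                        sasa$residue$insert, sep = "|")
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(retained))) {
    pair <- retained[i, , drop = FALSE]
    geom <- compute_geometry(s, pair, cfg)
    if (is.null(geom)) {
      excl[[length(excl) + 1L]] <- cbind(pair, reason = "no_bonded_carbon")
      next
    }
    ngb_n <- count_neighbors(s, pair$chain_n, pair$resno_n, pair$insert_n,
                             cfg = cfg)
    ngb_s <- count_neighbors(s, pair$chain_s, pair$resno_s, pair$insert_s,
                             cfg = cfg)
    if (is.na(ngb_n) || is.na(ngb_s)) {
      excl[[length(excl) + 1L]] <- cbind(pair, reason = "missing_calpha")
      next
    }
    if (is.na(pair$bfac_bdb_n) || is.na(pair$bfac_bdb_s)) {
      excl[[length(excl) + 1L]] <- cbind(pair, reason = "bdb_missing")
      next
    }
    sa_n <- sasa$atom$sasa[match(paste(pair$chain_n, pair$resno_n,
                                       pair$insert_n, pair$atom_n, sep = "|"),
                                 sasa_atom_key)]
    sa_s <- sasa$atom$sasa[match(paste(pair$chain_s, pair$resno_s,
                                       pair$insert_s, pair$atom_s, sep = "|"),
                                 sasa_atom_key)]
    sr_n <- sasa$residue$sasa[match(paste(pair$chain_n, pair$resno_n,
                                          pair$insert_n, sep = "|"),
                                    sasa_res_key)]
    sr_s <- sasa$residue$sasa[match(paste(pair$chain_s, pair$resno_s,
                                          pair$insert_s, sep = "|"),
                                    sasa_res_key)]
    if (anyNA(c(sa_n, sa_s, sr_n, sr_s))) {
      excl[[length(excl) + 1L]] <- cbind(pair, reason = "missing_sasa")
      next
    }
    desc <- c(geom["angle_csn"], geom["angle_cns"], geom["torsion_cs_nc"],
              geom["dist_cn"], geom["dist_sn"],
              bfac_pdb_n = pair$bfac_pdb_n, bfac_pdb_s = pair$bfac_pdb_s,
              bfac_bdb_n = pair$bfac_bdb_n, bfac_bdb_s = pair$bfac_bdb_s,
              ngb_n = ngb_n, ngb_s = ngb_s,
              sasa_atom_n = sa_n, sasa_atom_s = sa_s,
              sasa_res_n = sr_n, sasa_res_s = sr_s)
    ids <- data.frame(
      candidate_id = paste(pair$pdb_id,
                           pair$chain_s, pair$resid_s, pair$resno_s, pair$atom_s,
                           pair$chain_n, pair$resid_n, pair$resno_n, pair$atom_n,
                           sep = "/"),
      pair[, c("pdb_id", "chain_s", "resid_s", "resno_s", "insert_s", "atom_s",
               "chain_n", "resid_n", "resno_n", "insert_n", "atom_n")],
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- cbind(ids, as.data.frame(as.list(desc)))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    empty <- c(nos_id_columns(), nos_descriptor_names())
    as.data.frame(setNames(rep(list(character(0)), length(empty)), empty))
  }
  rownames(out) <- NULL
  stopifnot(all(nos_descriptor_names() %in% names(out)) || nrow(out) == 0)
  attr(out, "excluded") <- if (length(excl) > 0) do.call(rbind, excl) else NULL
  out
}

#' Write / read a descriptor matrix as TSV
#'
#' Lossless round trip: numeric columns are serialized with 17 significant
#' digits so that re-reading reproduces the doubles exactly.
#'
#' @param x Descriptor data.frame.
#' @param path Output path.
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
write_descriptor_tsv <- function(x, path) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  for (j in which(num)) y[[j]] <- sprintf("%.17g", y[[j]])
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_tsv
#' @export
read_descriptor_tsv <- function(path) {
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA)
  for (nm in intersect(names(out), c(nos_descriptor_names(), "dist_sn")))
    out[[nm]] <- as.numeric(out[[nm]])
  if ("insert_s" %in% names(out)) {
    out$insert_s[is.na(out$insert_s)] <- ""
    out$insert_n[is.na(out$insert_n)] <- ""
  }
  out
}
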