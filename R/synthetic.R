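# Synthetic fixture generation. Structures are built by inverse geometry:
# the four contact atoms C_S-S-N-C_N are placed so that descriptor
# extraction reproduces the requested dist(S,N), angle_CSN, angle_CNS and
# torsion exactly (to text precision), then minimal residue scaffolds with
# idealized bond lengths (peptide N-C 1.33 A, N-CA 1.46 A, SG-CB 1.81 A)
# are grown around them so that bonded-carbon resolution, packing counts
# and SASA are all well defined.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Natural-extension-reference-frame placement: returns the position d such
# that |d - c| = bond, angle(b, c, d) = angle_deg and the dihedral
# (a, b, c, d) = dihedral_deg under the right-hand-rule convention.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- vnorm(n)
  if (nn < 1e-10) stop("place_atom: reference atoms are collinear")
  n <- n / nn
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Specification of one planted S-N contact
#'
#' Defines the target geometry, occupancies, B-factors (deposited and BDB
#' variants), per-residue RSRZ values and entry metadata for one synthetic
#' structure built by [make_contact_structure()]. Default geometry is the
#' quantum-mechanically optimized Gly-NOS-Cys contact (dist(S,N) 2.70 A,
#' angle_CSN 94.02 deg, angle_CNS 95.11 deg).
#'
#' @param pdb_id Synthetic entry id (unique within a corpus).
#' @param partner Nitrogen-bearing residue: `"GLY"` (backbone N), `"LYS"`
#'   (side-chain NZ) or `"ARG"` (side-chain NH1).
#' @param dist_sn,angle_csn,angle_cns,torsion Target contact geometry
#'   (Angstrom / degrees).
#' @param occ_s,occ_n Occupancies of the target S and N atoms.
#' @param bfac_pdb_s,bfac_pdb_n Deposited B-factors of the target atoms.
#' @param bfac_bdb_s,bfac_bdb_n BDB B-factors of the target atoms.
#' @param bdb_missing_s,bdb_missing_n Omit the target atom from the BDB
#'   file (plants a `bdb_missing` rejection)?
#' @param rsrz_s,rsrz_n RSRZ of the sulfur- and nitrogen-bearing residues.
#' @param rsrz_missing_s,rsrz_missing_n Omit the residue's `rsrz` attribute
#'   from the validation report?
#' @param resolution,method Entry metadata (`method` `"xray"` or `"other"`).
#' @param close_contact Emit a validation-report clash record for the pair?
#' @param base_bfac B-factor given to all scaffold atoms.
#' @return list of class `"nos_contact_spec"`.
#' @export
contact_spec <- function(pdb_id = "syn1", partner = c("GLY", "LYS", "ARG"),
                         dist_sn = 2.70, angle_csn = 94.02,
                         angle_cns = 95.11, torsion = 75,
                         occ_s = 1.0, occ_n = 1.0,
                         bfac_pdb_s = 18, bfac_pdb_n = 16,
                         bfac_bdb_s = 20, bfac_bdb_n = 22,
                         bdb_missing_s = FALSE, bdb_missing_n = FALSE,
                         rsrz_s = 0.5, rsrz_n = 0.5,
                         rsrz_missing_s = FALSE, rsrz_missing_n = FALSE,
                         resolution = 1.80, method = "xray",
                         close_contact = FALSE, base_bfac = 15) {
  partner <- match.arg(partner)
  if (!is.finite(dist_sn) || dist_sn <= 0)
    stop("contact_spec: dist_sn must be positive")
  for (nm in c("angle_csn", "angle_cns")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 180)
      stop("contact_spec: ", nm, " must lie strictly inside (0, 180) degrees")
  }
  if (!is.finite(torsion) || torsion <= -180 || torsion > 180)
    stop("contact_spec: torsion must lie in (-180, 180]")
  for (nm in c("occ_s", "occ_n")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop("contact_spec: ", nm, " must lie in [0, 1]")
  }
  if (any(c(bfac_pdb_s, bfac_pdb_n, bfac_bdb_s, bfac_bdb_n, base_bfac) < 0))
    stop("contact_spec: B-factors must be >= 0")
  if (!is.finite(resolution) || resolution <= 0)
    stop("contact_spec: resolution must be positive")
  spec <- as.list(environment())
  class(spec) <- "nos_contact_spec"
  spec
}

# Grow the atom table for one spec. The contact atoms are exact; scaffolds
# use idealized geometry with fixed dihedrals chosen so that no unintended
# atom enters covalent or contact range of the target S and N.
build_contact_atoms <- function(spec) {
  a_csn <- spec$angle_csn * pi / 180
  S <- c(0, 0, 0)
  CB <- c(1.81, 0, 0)                                   # C_S (Cys CB)
  N <- spec$dist_sn * c(cos(a_csn), sin(a_csn), 0)      # target N

  add <- function(tab, atom, element, resid, resno, xyz, o = 1, b = spec$base_bfac) {
    rbind(tab, data.frame(atom = atom, element = element, resid = resid,
                          chain = "A", resno = resno, insert = "", alt = "",
                          x = xyz[1], y = xyz[2], z = xyz[3], o = o, b = b,
                          stringsAsFactors = FALSE))
  }
  tab <- NULL

  if (spec$partner == "GLY") {
    CN <- place_atom(CB, S, N, 1.33, spec$angle_cns, spec$torsion)  # Gly(t-1) C
    CA2 <- place_atom(S, CN, N, 1.46, 121, 180)
    C2 <- place_atom(CN, N, CA2, 1.52, 110, 180)
    O2 <- place_atom(N, CA2, C2, 1.23, 120, 0)
    CA1 <- place_atom(CA2, N, CN, 1.52, 116, 180)
    O1 <- place_atom(N, CA1, CN, 1.23, 121, 180)
    # keep the preceding residue's backbone N out of contact range of S:
    # try dihedrals in a fixed order and take the first safe placement
    N1 <- NULL
    for (dh in c(180, 120, -120, 60, -60)) {
      cand <- place_atom(N, CN, CA1, 1.46, 110, dh)
      if (vnorm(cand - S) > 3.4) { N1 <- cand; break }
    }
    if (is.null(N1))
      stop("build_contact_atoms: cannot place the preceding backbone N ",
           "outside contact range of S for this geometry")
    tab <- add(tab, "N", "N", "GLY", 1, N1)
    tab <- add(tab, "CA", "C", "GLY", 1, CA1)
    tab <- add(tab, "C", "C", "GLY", 1, CN)
    tab <- add(tab, "O", "O", "GLY", 1, O1)
    tab <- add(tab, "N", "N", "GLY", 2, N, o = spec$occ_n, b = spec$bfac_pdb_n)
    tab <- add(tab, "CA", "C", "GLY", 2, CA2)
    tab <- add(tab, "C", "C", "GLY", 2, C2)
    tab <- add(tab, "O", "O", "GLY", 2, O2)
    n_resno <- 2L; n_atom_name <- "N"
  } else if (spec$partner == "LYS") {
    CE <- place_atom(CB, S, N, 1.49, spec$angle_cns, spec$torsion)
    CD <- place_atom(S, N, CE, 1.52, 112, 180)
    CG <- place_atom(N, CE, CD, 1.52, 112, 180)
    CB2 <- place_atom(CE, CD, CG, 1.52, 112, 180)
    CA2 <- place_atom(CD, CG, CB2, 1.53, 112, 180)
    N2 <- place_atom(CG, CB2, CA2, 1.46, 110, 60)
    C2 <- place_atom(CG, CB2, CA2, 1.52, 110, -60)
    O2 <- place_atom(CB2, CA2, C2, 1.23, 120, 0)
    tab <- add(tab, "N", "N", "LYS", 2, N2)
    tab <- add(tab, "CA", "C", "LYS", 2, CA2)
    tab <- add(tab, "C", "C", "LYS", 2, C2)
    tab <- add(tab, "O", "O", "LYS", 2, O2)
    tab <- add(tab, "CB", "C", "LYS", 2, CB2)
    tab <- add(tab, "CG", "C", "LYS", 2, CG)
    tab <- add(tab, "CD", "C", "LYS", 2, CD)
    tab <- add(tab, "CE", "C", "LYS", 2, CE)
    tab <- add(tab, "NZ", "N", "LYS", 2, N, o = spec$occ_n, b = spec$bfac_pdb_n)
    n_resno <- 2L; n_atom_name <- "NZ"
  } else {  # ARG, side-chain NH1
    CZ <- place_atom(CB, S, N, 1.33, spec$angle_cns, spec$torsion)
    # guanidinium plane tilted out of the S plane (dihedral +/-90) so that
    # the two untargeted nitrogens stay out of contact range of S
    NH2 <- place_atom(S, N, CZ, 1.33, 120, 90)
    NE <- place_atom(S, N, CZ, 1.33, 120, -90)
    CD <- place_atom(N, CZ, NE, 1.46, 124, 180)
    CG <- place_atom(CZ, NE, CD, 1.52, 112, 180)
    CB2 <- place_atom(NE, CD, CG, 1.52, 112, 180)
    CA2 <- place_atom(CD, CG, CB2, 1.53, 112, 180)
    N2 <- place_atom(CG, CB2, CA2, 1.46, 110, 60)
    C2 <- place_atom(CG, CB2, CA2, 1.52, 110, -60)
    O2 <- place_atom(CB2, CA2, C2, 1.23, 120, 0)
    tab <- add(tab, "N", "N", "ARG", 2, N2)
    tab <- add(tab, "CA", "C", "ARG", 2, CA2)
    tab <- add(tab, "C", "C", "ARG", 2, C2)
    tab <- add(tab, "O", "O", "ARG", 2, O2)
    tab <- add(tab, "CB", "C", "ARG", 2, CB2)
    tab <- add(tab, "CG", "C", "ARG", 2, CG)
    tab <- add(tab, "CD", "C", "ARG", 2, CD)
    tab <- add(tab, "NE", "N", "ARG", 2, NE)
    tab <- add(tab, "CZ", "C", "ARG", 2, CZ)
    tab <- add(tab, "NH1", "N", "ARG", 2, N, o = spec$occ_n, b = spec$bfac_pdb_n)
    tab <- add(tab, "NH2", "N", "ARG", 2, NH2)
    n_resno <- 2L; n_atom_name <- "NH1"
  }

  # cysteine scaffold (sulfur donor), residue 10 on the same chain
  CA_c <- place_atom(N, S, CB, 1.53, 114, -60)
  N_c <- place_atom(S, CB, CA_c, 1.46, 110, 180)
  C_c <- place_atom(S, CB, CA_c, 1.52, 110, 60)
  O_c <- place_atom(CB, CA_c, C_c, 1.23, 120, 0)
  tab <- add(tab, "N", "N", "CYS", 10, N_c)
  tab <- add(tab, "CA", "C", "CYS", 10, CA_c)
  tab <- add(tab, "C", "C", "CYS", 10, C_c)
  tab <- add(tab, "O", "O", "CYS", 10, O_c)
  tab <- add(tab, "CB", "C", "CYS", 10, CB)
  tab <- add(tab, "SG", "S", "CYS", 10, S, o = spec$occ_s, b = spec$bfac_pdb_s)

  # construction invariant: the planted pair must be the only S-N contact
  other_n <- tab$element == "N" &
    !(tab$resno == n_resno & tab$atom == n_atom_name) & tab$resid != "CYS"
  if (any(other_n)) {
    dS <- sqrt((tab$x[other_n] - S[1])^2 + (tab$y[other_n] - S[2])^2 +
                 (tab$z[other_n] - S[3])^2)
    if (any(dS <= 3.3))
      stop("build_contact_atoms: a scaffold nitrogen falls within contact ",
           "range of S (geometry not realizable without a second contact)")
  }

  attr(tab, "target") <- list(
    s = list(chain = "A", resno = 10L, insert = "", atom = "SG", resid = "CYS"),
    n = list(chain = "A", resno = n_resno, insert = "", atom = n_atom_name,
             resid = spec$partner)
  )
  tab
}

format_mmcif <- function(atoms, spec) {
  method_str <- if (spec$method == "xray") "X-RAY DIFFRACTION" else "ELECTRON MICROSCOPY"
  hdr <- c(
    paste0("data_", spec$pdb_id),
    "#",
    sprintf("_exptl.method '%s'", method_str),
    sprintf("_refine.ls_d_res_high %.2f", spec$resolution),
    "#",
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"))
  )
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM %d %s %s %s %s %s 1 %d %s %.6f %.6f %.6f %.2f %.2f %d %s %s %s 1",
            i, a$element, a$atom,
            ifelse(a$alt == "", ".", a$alt),
            a$resid, a$chain, a$resno,
            ifelse(a$insert == "", "?", a$insert),
            a$x, a$y, a$z, a$o, a$b,
            a$resno, a$resid, a$chain, a$atom)
  }, character(1))
  c(hdr, rows, "#")
}

format_pdb_atom_line <- function(i, a, b_override = NULL) {
  b <- if (is.null(b_override)) a$b else b_override
  name <- if (nchar(a$atom) < 4) sprintf(" %-3s", a$atom) else a$atom
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, name, ifelse(a$alt == "", " ", a$alt), a$resid, a$chain,
          a$resno, ifelse(a$insert == "", " ", a$insert),
          a$x, a$y, a$z, a$o, b, a$element)
}

format_bdb <- function(atoms, spec, target) {
  lines <- character(0)
  k <- 0L
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    is_s <- a$chain == target$s$chain && a$resno == target$s$resno &&
      a$atom == target$s$atom
    is_n <- a$chain == target$n$chain && a$resno == target$n$resno &&
      a$atom == target$n$atom
    if (is_s && spec$bdb_missing_s) next
    if (is_n && spec$bdb_missing_n) next
    b <- if (is_s) spec$bfac_bdb_s else if (is_n) spec$bfac_bdb_n else a$b
    k <- k + 1L
    lines <- c(lines, format_pdb_atom_line(k, a, b))
  }
  c(sprintf("REMARK   BDB companion file for %s", spec$pdb_id), lines, "END")
}

format_validation_xml <- function(atoms, spec, target) {
  rk <- unique(data.frame(chain = atoms$chain, resno = atoms$resno,
                          insert = atoms$insert, resid = atoms$resid,
                          stringsAsFactors = FALSE))
  res_lines <- vapply(seq_len(nrow(rk)), function(i) {
    r <- rk[i, ]
    is_s <- r$chain == target$s$chain && r$resno == target$s$resno
    is_n <- r$chain == target$n$chain && r$resno == target$n$resno
    rsrz <- if (is_s) spec$rsrz_s else if (is_n) spec$rsrz_n else 0.30
    omit <- (is_s && spec$rsrz_missing_s) || (is_n && spec$rsrz_missing_n)
    sprintf("    <ModelledSubgroup chain=\"%s\" resnum=\"%d\" icode=\"%s\" resname=\"%s\"%s/>",
            r$chain, r$resno, ifelse(r$insert == "", " ", r$insert), r$resid,
            if (omit) "" else sprintf(" rsrz=\"%.2f\"", rsrz))
  }, character(1))
  clash <- if (spec$close_contact) {
    sprintf(paste0("    <clash chain1=\"%s\" resnum1=\"%d\" icode1=\" \" atom1=\"%s\" ",
                   "chain2=\"%s\" resnum2=\"%d\" icode2=\" \" atom2=\"%s\" dist=\"%.2f\"/>"),
            target$s$chain, target$s$resno, target$s$atom,
            target$n$chain, target$n$resno, target$n$atom, spec$dist_sn)
  } else character(0)
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<wwPDB_validation_information>",
    sprintf("  <Entry pdbid=\"%s\">", spec$pdb_id),
    res_lines, clash,
    "  </Entry>",
    "</wwPDB_validation_information>")
}

# Expected screening outcome for a spec, mirroring the filter precedence.
expected_outcome <- function(spec, cfg = screening_config()) {
  if (spec$method != "xray") return(list(retained = FALSE, reason = "method"))
  if (spec$resolution > cfg$max_resolution)
    return(list(retained = FALSE, reason = "resolution"))
  if (spec$dist_sn > cfg$max_sn_dist + cfg$dist_epsilon)
    return(list(retained = FALSE, reason = "no_contact"))
  if (!(spec$occ_s > cfg$min_occupancy) || !(spec$occ_n > cfg$min_occupancy))
    return(list(retained = FALSE, reason = "occupancy"))
  if (spec$rsrz_missing_s || spec$rsrz_missing_n)
    return(list(retained = FALSE, reason = "missing_rsrz"))
  if (!(spec$rsrz_s < cfg$max_rsrz) || !(spec$rsrz_n < cfg$max_rsrz))
    return(list(retained = FALSE, reason = "rsrz"))
  if (spec$bdb_missing_s || spec$bdb_missing_n)
    return(list(retained = FALSE, reason = "bdb_missing"))
  list(retained = TRUE, reason = NA_character_)
}

#' Build one synthetic structure with a planted S-N contact
#'
#' Inverse-geometry construction: places the contact atoms so that the
#' extracted descriptors reproduce the spec geometry to text precision
#' (<= 1e-3), then serializes the entry as mmCIF text, a BDB companion file
#' and a validation-report XML carrying the requested RSRZ values and
#' optional clash record.
#'
#' @param spec A [contact_spec()].
#' @param cfg A [screening_config()] used to derive the expected screening
#'   outcome recorded alongside the files.
#' @return list with `mmcif`, `bdb`, `validation` (character vectors of
#'   lines), `atoms` (the atom table), `target` (keys of the planted S and
#'   N atoms) and `expected` (planted screening outcome + reason).
#' @export
make_contact_structure <- function(spec, cfg = screening_config()) {
  stopifnot(inherits(spec, "nos_contact_spec"))
  atoms <- build_contact_atoms(spec)
  target <- attr(atoms, "target")
  list(mmcif = format_mmcif(atoms, spec),
       bdb = format_bdb(atoms, spec, target),
       validation = format_validation_xml(atoms, spec, target),
       atoms = atoms, target = target,
       expected = expected_outcome(spec, cfg))
}

#' Write a corpus of synthetic entries to disk
#'
#' Lays out one directory per entry (`<id>/structure.cif`, `<id>/bdb.pdb`,
#' `<id>/validation.xml`), mirroring the layout the screening stage reads,
#' and records the planted truth (retain/reject and the expected first
#' rejection reason) in a manifest.
#'
#' @param specs list of [contact_spec()] objects with unique ids.
#' @param dir Output directory.
#' @param cfg A [screening_config()].
#' @return The manifest data.frame (also written to `dir/manifest.tsv`),
#'   invisibly.
#' @export
make_corpus <- function(specs, dir, cfg = screening_config()) {
  ids <- vapply(specs, function(s) s$pdb_id, character(1))
  if (anyDuplicated(ids))
    stop("make_corpus: duplicate entry ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    files <- make_contact_structure(spec, cfg)
    edir <- file.path(dir, spec$pdb_id)
    dir.create(edir, showWarnings = FALSE)
    writeLines(files$mmcif, file.path(edir, "structure.cif"))
    writeLines(files$bdb, file.path(edir, "bdb.pdb"))
    writeLines(files$validation, file.path(edir, "validation.xml"))
    rows[[i]] <- data.frame(
      pdb_id = spec$pdb_id, partner = spec$partner, dist_sn = spec$dist_sn,
      expect_retained = files$expected$retained,
      expect_reason = ifelse(is.na(files$expected$reason), "",
                             files$expected$reason),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Descriptor matrix with planted cluster structure
#'
#' Draws rows from isotropic Gaussian blobs on an informative descriptor
#' subset (all other descriptors are i.i.d. standard normal noise for every
#' row), and appends reference rows drawn from their assigned blob. This
#' emulates the statistical structure the subset search is built to find:
#' separated clusters with the verified reference linkages concentrated in
#' one of them.
#'
#' @param n_rows Integer vector: rows per blob.
#' @param centers Matrix (blobs x length(informative)) of blob centers on
#'   the informative descriptors; a vector is recycled to one row per blob.
#' @param informative Indices (in 1..15) of the informative descriptors.
#' @param spread Gaussian standard deviation on the informative descriptors
#'   (scalar or per blob).
#' @param n_reference Number of reference rows to append.
#' @param ref_blob Blob index the reference rows are drawn from.
#' @param seed Integer seed (the matrix is byte-identical across runs for a
#'   fixed seed).
#' @return list with `X` (matrix, 15 named descriptor columns), `ref`
#'   (logical flags) and `blob` (planted blob index per row).
#' @export
make_descriptor_blobs <- function(n_rows, centers, informative,
                                  spread = 1, n_reference = 0,
                                  ref_blob = 1, seed = 1) {
  k <- length(n_rows)
  if (is.vector(centers) && !is.matrix(centers))
    centers <- matrix(centers, nrow = k, ncol = length(centers), byrow = TRUE)
  stopifnot(nrow(centers) == k, ncol(centers) == length(informative),
            all(informative >= 1), all(informative <= 15))
  if (n_reference > sum(n_rows))
    stop("make_descriptor_blobs: n_reference exceeds the number of data rows")
  if (n_reference > 0 && (ref_blob < 1 || ref_blob > k))
    stop("make_descriptor_blobs: ref_blob out of range")
  spread <- rep_len(spread, k)
  set.seed(as.integer(seed))
  n_total <- sum(n_rows) + n_reference
  X <- matrix(rnorm(n_total * 15), n_total, 15)
  colnames(X) <- nos_descriptor_names()
  blob <- c(rep(seq_len(k), n_rows), rep(ref_blob, n_reference))
  for (b in seq_len(k)) {
    rows <- which(blob == b)
    X[rows, informative] <- matrix(centers[b, ], length(rows),
                                   length(informative), byrow = TRUE) +
      spread[b] * matrix(rnorm(length(rows) * length(informative)),
                         length(rows), length(informative))
  }
  ref <- c(rep(FALSE, sum(n_rows)), rep(TRUE, n_reference))
  list(X = X, ref = ref, blob = blob)
}

#' Reference descriptor vectors for injection
#'
#' Draws `n` reference descriptor rows around a 15-component template, one
#' standard deviation per descriptor. Used to emulate the experimentally
#' verified linkages whose descriptor vectors are appended to every
#' pair-class matrix before embedding.
#'
#' @param center Named numeric vector of length 15 (names =
#'   [nos_descriptor_names()]).
#' @param sd Numeric vector of per-descriptor standard deviations
#'   (recycled).
#' @param n Number of reference rows.
#' @param seed Integer seed.
#' @return data.frame with `candidate_id` and the 15 descriptor columns.
#' @export
make_reference_vectors <- function(center, sd = 1, n = 74, seed = 1) {
  nms <- nos_descriptor_names()
  stopifnot(all(nms %in% names(center)))
  sd <- rep_len(sd, 15)
  set.seed(as.integer(seed))
  X <- matrix(rnorm(n * 15), n, 15)
  X <- sweep(X, 2, sd, "*")
  X <- sweep(X, 2, as.numeric(center[nms]), "+")
  colnames(X) <- nms
  out <- cbind(data.frame(candidate_id = sprintf("ref/%03d", seq_len(n)),
                          stringsAsFactors = FALSE),
               as.data.frame(X))
  out
}

#' Example corpus: a scaled-down screening study
#'
#' Builds a complete synthetic study at desk scale: `n_nos` entries whose
#' planted contact matches the optimized NOS geometry (dist(S,N) ~ 2.70 A,
#' angle_CSN ~ 94 deg) with low, consistent B-factors; `n_background`
#' entries with wide-angle, longer, high-B-factor contacts that pass every
#' quality filter but do not resemble NOS linkages; and eight entries
#' planted to fail one filter each (resolution x2, method, occupancy x2,
#' RSRZ, BDB availability, distance). Also draws `n_reference` reference
#' descriptor vectors around the NOS geometry, with realistic spread on the
#' uninformative descriptors, for injection into the subset search.
#'
#' @param dir Output directory for the corpus files.
#' @param n_nos Number of NOS-like entries. Default 5.
#' @param n_background Number of filter-passing non-NOS entries. Default 37.
#' @param n_reference Number of reference vectors. Default 74.
#' @param seed Integer seed.
#' @return list with `manifest` (from [make_corpus()]), `reference` (from
#'   [make_reference_vectors()]) and `nos_ids` (the planted NOS entry ids).
#' @export
make_example_corpus <- function(dir, n_nos = 5, n_background = 37,
                                n_reference = 74, seed = 1) {
  set.seed(as.integer(seed))
  specs <- list()
  for (i in seq_len(n_nos)) {
    specs[[length(specs) + 1L]] <- contact_spec(
      pdb_id = sprintf("nos%02d", i), partner = "GLY",
      dist_sn = round(rnorm(1, 2.70, 0.02), 3),
      angle_csn = round(rnorm(1, 94.0, 1.2), 2),
      angle_cns = round(rnorm(1, 95.1, 1.2), 2),
      torsion = round(runif(1, -170, 170), 1),
      occ_s = round(runif(1, 0.92, 1.0), 2),
      occ_n = round(runif(1, 0.92, 1.0), 2),
      bfac_pdb_s = round(rnorm(1, 18, 2), 2),
      bfac_pdb_n = round(rnorm(1, 16, 2), 2),
      bfac_bdb_s = round(rnorm(1, 20, 2), 2),
      bfac_bdb_n = round(rnorm(1, 22, 2), 2),
      rsrz_s = round(runif(1, 0.1, 1.2), 2),
      rsrz_n = round(runif(1, 0.1, 1.2), 2))
  }
  for (i in seq_len(n_background)) {
    specs[[length(specs) + 1L]] <- contact_spec(
      pdb_id = sprintf("bkg%02d", i), partner = "GLY",
      dist_sn = round(runif(1, 2.90, 3.18), 3),
      angle_csn = round(runif(1, 140, 172), 2),
      angle_cns = round(runif(1, 115, 160), 2),
      torsion = round(runif(1, -170, 170), 1),
      occ_s = round(runif(1, 0.85, 1.0), 2),
      occ_n = round(runif(1, 0.85, 1.0), 2),
      bfac_pdb_s = round(rnorm(1, 55, 6), 2),
      bfac_pdb_n = round(rnorm(1, 58, 6), 2),
      bfac_bdb_s = round(rnorm(1, 58, 6), 2),
      bfac_bdb_n = round(rnorm(1, 62, 6), 2),
      rsrz_s = round(runif(1, 0.1, 1.8), 2),
      rsrz_n = round(runif(1, 0.1, 1.8), 2))
  }
  specs <- c(specs, list(
    contact_spec(pdb_id = "rej01", resolution = 2.50),
    contact_spec(pdb_id = "rej02", resolution = 2.05),
    contact_spec(pdb_id = "rej03", method = "other"),
    contact_spec(pdb_id = "rej04", occ_n = 0.70),
    contact_spec(pdb_id = "rej05", occ_s = 0.80),
    contact_spec(pdb_id = "rej06", rsrz_s = 2.50),
    contact_spec(pdb_id = "rej07", bdb_missing_n = TRUE),
    contact_spec(pdb_id = "rej08", dist_sn = 3.50)))
  manifest <- make_corpus(specs, dir)
  template <- c(angle_csn = 94.0, angle_cns = 95.1, torsion_cs_nc = 0,
                dist_cn = 3.35, dist_sn = 2.70,
                bfac_pdb_n = 16, bfac_pdb_s = 18,
                bfac_bdb_n = 22, bfac_bdb_s = 20,
                ngb_n = 2, ngb_s = 2,
                sasa_atom_n = 2.2, sasa_atom_s = 41,
                sasa_res_n = 105, sasa_res_s = 148)
  # spreads: tight on the NOS-defining geometry and B-factors, wide on the
  # torsion (no preferred rotamer) and the context descriptors
  sds <- c(angle_csn = 1.5, angle_cns = 1.5, torsion_cs_nc = 100,
           dist_cn = 0.08, dist_sn = 0.03,
           bfac_pdb_n = 2.5, bfac_pdb_s = 2.5,
           bfac_bdb_n = 2.5, bfac_bdb_s = 2.5,
           ngb_n = 0.5, ngb_s = 0.5,
           sasa_atom_n = 1.5, sasa_atom_s = 5,
           sasa_res_n = 8, sasa_res_s = 8)
  nms <- nos_descriptor_names()
  reference <- make_reference_vectors(template[nms], sds[nms],
                                      n = n_reference, seed = seed + 1L)
  list(manifest = manifest, reference = reference,
       nos_ids = sprintf("nos%02d", seq_len(n_nos)))
}
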