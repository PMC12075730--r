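# Reading of the three input sources: coordinate files (mmCIF / PDB),
# BDB companion files (PDB dialect, recalibrated B-factor column) and
# wwPDB validation reports (XML subset: per-residue RSRZ + clash records).

STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a structure model
#'
#' Low-level constructor used by [read_structure()] and by the synthetic
#' fixture generator. `atoms` must contain the columns `atom`, `element`,
#' `resid`, `chain`, `resno`, `insert`, `alt`, `x`, `y`, `z`, `o`, `b`.
#' Alternate locations are expected to be already collapsed (one row per
#' atom key).
#'
#' @param atoms data.frame of atom records (one row per atom).
#' @param pdb_id Entry identifier (stored lowercased).
#' @param method `"xray"`, `"other"`, or `NA` when unknown.
#' @param resolution Resolution in Angstrom, or `NA` when absent.
#' @return An object of class `"nos_structure"`.
#' @export
nos_structure <- function(atoms, pdb_id = "xxxx", method = NA_character_,
                          resolution = NA_real_) {
  needed <- c("atom", "element", "resid", "chain", "resno", "insert", "alt",
              "x", "y", "z", "o", "b")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0)
    stop("nos_structure: atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0)
    stop("nos_structure: empty structure (zero atoms)")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop("nos_structure: non-finite coordinates")
  if (any(is.na(atoms$o)) || any(atoms$o < 0 | atoms$o > 1))
    stop("nos_structure: occupancies must lie in [0, 1]")
  if (any(is.na(atoms$b)) || any(atoms$b < 0))
    stop("nos_structure: B-factors must be >= 0")
  rownames(atoms) <- NULL
  structure(
    list(pdb_id = tolower(pdb_id), method = method,
         resolution = resolution, atoms = atoms),
    class = "nos_structure"
  )
}

#' @export
print.nos_structure <- function(x, ...) {
  cat(sprintf("<nos_structure> %s | method: %s | resolution: %s A | %d atoms, %d residues\n",
              x$pdb_id, x$method,
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              nrow(x$atoms), length(unique(residue_key(x$atoms)))))
  invisible(x)
}

# Residue key: chain / author residue number / insertion code / residue name.
residue_key <- function(df) {
  paste(df$chain, df$resno, df$insert, df$resid, sep = "|")
}

atom_key <- function(df) {
  paste(df$chain, df$resno, df$insert, df$atom, sep = "|")
}

# Collapse alternate locations: per atom key keep the highest-occupancy
# conformer; ties broken by lexicographically smallest altloc.
collapse_altlocs <- function(atoms) {
  key <- paste(atom_key(atoms), atoms$resid, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

# Muffle bio3d's advisory warnings (beta read.cif notice, absent
# helix/sheet records) while letting real warnings through.
quiet_bio3d <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    msg <- conditionMessage(w)
    if (grepl("beta version|helix/sheet|no helix|no sheet", msg, ignore.case = TRUE))
      invokeRestart("muffleWarning")
  })
}

# Scan file text for experimental method and resolution. mmCIF: key-value
# items _exptl.method and _refine.ls_d_res_high / _reflns.d_resolution_high.
# PDB: EXPDTA and REMARK 2 RESOLUTION lines.
scan_metadata <- function(lines, format) {
  method <- NA_character_
  resolution <- NA_real_
  if (format == "mmcif") {
    m <- grep("^_exptl\\.method", lines, value = TRUE)
    if (length(m) > 0) {
      val <- sub("^_exptl\\.method\\s+", "", m[1])
      val <- gsub("^['\"]|['\"]$", "", trimws(val))
      method <- if (grepl("X-RAY", toupper(val), fixed = TRUE)) "xray" else "other"
    }
    for (item in c("^_refine\\.ls_d_res_high", "^_reflns\\.d_resolution_high")) {
      r <- grep(item, lines, value = TRUE)
      if (length(r) > 0) {
        val <- suppressWarnings(as.numeric(sub("^\\S+\\s+", "", trimws(r[1]))))
        if (is.finite(val)) { resolution <- val; break }
      }
    }
  } else {
    m <- grep("^EXPDTA", lines, value = TRUE)
    if (length(m) > 0) {
      method <- if (grepl("X-RAY", toupper(m[1]), fixed = TRUE)) "xray" else "other"
    }
    r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(r) > 0) {
      val <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", r[1])))
      if (is.finite(val)) resolution <- val
    }
  }
  list(method = method, resolution = resolution)
}

#' Read a macromolecular structure (mmCIF or PDB)
#'
#' Parses the first model of a coordinate file into a [nos_structure()].
#' Alternate locations are collapsed to the highest-occupancy conformer
#' (ties broken by altloc letter); insertion codes and author residue
#' numbering are preserved as-is. Experimental method and resolution are
#' read from the header when present and flagged `NA` otherwise.
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"` (by extension, then content sniffing), `"mmcif"`,
#'   or `"pdb"`.
#' @return A `"nos_structure"` object.
#' @export
#' @examples
#' spec <- contact_spec(pdb_id = "ex01")
#' files <- make_contact_structure(spec)
#' tf <- tempfile(fileext = ".cif"); writeLines(files$mmcif, tf)
#' s <- read_structure(tf)
#' s$resolution
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(grepl("_atom_site\\.", lines))) "mmcif"
      else "pdb"
  }
  meta <- scan_metadata(lines, format)

  if (format == "pdb") {
    coord <- grep("^(ATOM|HETATM)", lines)
    short <- coord[nchar(lines[coord]) < 66]
    if (length(short) > 0)
      stop(sprintf("read_structure: malformed/truncated %s record at line %d",
                   "ATOM", short[1]))
  }
  parsed <- tryCatch(
    quiet_bio3d(
      if (format == "mmcif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE)
    ),
    error = function(e) stop("read_structure: cannot parse '", path,
                             "' as ", format, ": ", conditionMessage(e))
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0)
    stop("read_structure: empty structure (zero atoms) in ", path)
  atoms <- data.frame(
    atom = as.character(at$elety),
    element = ifelse(is.na(at$elesy) | !(toupper(at$elesy) %in%
                       c("C", "N", "O", "S", "H", "P", "D", "SE", "FE", "ZN", "MG", "MN", "CA", "NA", "K", "CL")),
                     toupper(substr(gsub("[0-9]", "", as.character(at$elety)), 1, 1)),
                     toupper(as.character(at$elesy))),
    resid = as.character(at$resid),
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = as.numeric(at$o), b = as.numeric(at$b),
    stringsAsFactors = FALSE
  )
  atoms <- collapse_altlocs(atoms)
  pdb_id <- tolower(sub("\\..*$", "", basename(path)))
  if (format == "mmcif") {
    blk <- grep("^data_", lines, value = TRUE)
    if (length(blk) > 0 && nchar(sub("^data_", "", blk[1])) > 0)
      pdb_id <- tolower(sub("^data_", "", blk[1]))
  }
  nos_structure(atoms, pdb_id = pdb_id, method = meta$method,
                resolution = meta$resolution)
}

#' Entry-level metadata filter
#'
#' A structure passes when it was determined by X-ray diffraction and its
#' resolution is at or below `cfg$max_resolution` (inclusive). The first
#' failed criterion is reported as the reason; a missing resolution fails
#' with reason `"missing_resolution"`.
#'
#' @param s A `"nos_structure"`.
#' @param cfg A [screening_config()].
#' @return list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
passes_entry_filters <- function(s, cfg = screening_config()) {
  stopifnot(inherits(s, "nos_structure"))
  if (is.na(s$method) || s$method != "xray")
    return(list(pass = FALSE, reason = "method"))
  if (is.na(s$resolution))
    return(list(pass = FALSE, reason = "missing_resolution"))
  if (s$resolution > cfg$max_resolution)
    return(list(pass = FALSE, reason = "resolution"))
  list(pass = TRUE, reason = NA_character_)
}

#' Read a BDB companion file
#'
#' BDB files are PDB-format coordinate files whose B-factor column holds
#' consistent full isotropic B-factors. Only the atom records are consumed;
#' each ATOM/HETATM line is strictly validated (fixed columns, numeric
#' B-factor >= 0) and a malformed line raises a parse error naming the line
#' number. Alternate locations are collapsed with the same highest-occupancy
#' policy as [read_structure()].
#'
#' @param path Path to the BDB file.
#' @return A `"bdb_table"`: data.frame with columns `chain`, `resno`,
#'   `insert`, `atom`, `alt`, `b` and attribute `source = "bdb"`.
#' @export
read_bdb_bfactors <- function(path) {
  if (!file.exists(path)) stop("read_bdb_bfactors: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^(ATOM|HETATM)", lines)
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ln <- lines[idx[i]]
    if (nchar(ln) < 66)
      stop(sprintf("read_bdb_bfactors: malformed ATOM line %d (too short)", idx[i]))
    b <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (is.na(b) || is.na(o) || is.na(resno))
      stop(sprintf("read_bdb_bfactors: malformed ATOM line %d (non-numeric field)", idx[i]))
    if (b < 0)
      stop(sprintf("read_bdb_bfactors: negative B-factor at line %d", idx[i]))
    rows[[i]] <- data.frame(
      chain = trimws(substr(ln, 22, 22)),
      resno = resno,
      insert = trimws(substr(ln, 27, 27)),
      atom = trimws(substr(ln, 13, 16)),
      alt = trimws(substr(ln, 17, 17)),
      o = o, b = b,
      stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), insert = character(),
               atom = character(), alt = character(), o = numeric(),
               b = numeric(), stringsAsFactors = FALSE)
  if (nrow(tab) > 0) {
    key <- paste(tab$chain, tab$resno, tab$insert, tab$atom, sep = "|")
    if (anyDuplicated(key)) {
      ord <- order(key, -tab$o, tab$alt)
      tab <- tab[ord, , drop = FALSE]
      tab <- tab[!duplicated(key[ord]), , drop = FALSE]
    }
  }
  tab$o <- NULL
  rownames(tab) <- NULL
  attr(tab, "source") <- "bdb"
  class(tab) <- c("bdb_table", "data.frame")
  tab
}

#' Look up a B-factor in a BDB table
#'
#' Returns the B-factor for the atom keyed by chain, author residue number,
#' insertion code and atom name, or `NA_real_` when the atom is absent from
#' the table. Absence is always reported as `NA`, never as a default value.
#'
#' @param tab A `"bdb_table"` from [read_bdb_bfactors()].
#' @param chain,resno,insert,atom Atom key components (vectorized).
#' @return Numeric vector of B-factors (`NA` where absent).
#' @export
bfactor_lookup <- function(tab, chain, resno, insert = "", atom) {
  key <- paste(tab$chain, tab$resno, tab$insert, tab$atom, sep = "|")
  q <- paste(chain, resno, insert, atom, sep = "|")
  tab$b[match(q, key)]
}

#' Read a wwPDB-style validation report
#'
#' Consumes the subset of the validation XML that the pipeline needs:
#' per-residue RSRZ values carried as `rsrz` attributes on
#' `ModelledSubgroup` elements, and close-contact ("clash") records carrying
#' two atom references and the observed distance. Residues without an `rsrz`
#' attribute are absent from the map (never defaulted to 0); clash pairs are
#' stored unordered and deduplicated.
#'
#' @param path Path to the validation XML file.
#' @return A `"nos_validation"` list with elements `rsrz` (data.frame
#'   `chain`, `resno`, `insert`, `resid`, `rsrz`) and `close_contacts`
#'   (data.frame `chain1`, `resno1`, `insert1`, `atom1`, `chain2`, `resno2`,
#'   `insert2`, `atom2`, `dist`).
#' @export
read_validation_report <- function(path) {
  if (!file.exists(path)) stop("read_validation_report: file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("read_validation_report: XML parse failure in '",
                                           path, "': ", conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (!identical(root, "wwPDB_validation_information"))
    stop("read_validation_report: unexpected root element <", root,
         ">; expected <wwPDB_validation_information>")
  subgroups <- xml2::xml_find_all(doc, ".//ModelledSubgroup")
  rsrz_rows <- list()
  for (node in subgroups) {
    r <- xml2::xml_attr(node, "rsrz")
    if (is.na(r)) next
    ic <- xml2::xml_attr(node, "icode")
    rsrz_rows[[length(rsrz_rows) + 1L]] <- data.frame(
      chain = xml2::xml_attr(node, "chain"),
      resno = as.integer(xml2::xml_attr(node, "resnum")),
      insert = ifelse(is.na(ic) | ic == " ", "", ic),
      resid = xml2::xml_attr(node, "resname"),
      rsrz = as.numeric(r),
      stringsAsFactors = FALSE
    )
  }
  rsrz <- if (length(rsrz_rows) > 0) do.call(rbind, rsrz_rows) else
    data.frame(chain = character(), resno = integer(), insert = character(),
               resid = character(), rsrz = numeric(), stringsAsFactors = FALSE)

  clashes <- xml2::xml_find_all(doc, ".//clash")
  cc_rows <- list()
  for (node in clashes) {
    a <- function(nm) {
      v <- xml2::xml_attr(node, nm)
      ifelse(is.na(v) | v == " ", "", v)
    }
    cc_rows[[length(cc_rows) + 1L]] <- data.frame(
      chain1 = a("chain1"), resno1 = as.integer(xml2::xml_attr(node, "resnum1")),
      insert1 = a("icode1"), atom1 = a("atom1"),
      chain2 = a("chain2"), resno2 = as.integer(xml2::xml_attr(node, "resnum2")),
      insert2 = a("icode2"), atom2 = a("atom2"),
      dist = as.numeric(xml2::xml_attr(node, "dist")),
      stringsAsFactors = FALSE
    )
  }
  cc <- if (length(cc_rows) > 0) do.call(rbind, cc_rows) else
    data.frame(chain1 = character(), resno1 = integer(), insert1 = character(),
               atom1 = character(), chain2 = character(), resno2 = integer(),
               insert2 = character(), atom2 = character(), dist = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(cc) > 0) {
    k1 <- paste(cc$chain1, cc$resno1, cc$insert1, cc$atom1, sep = "|")
    k2 <- paste(cc$chain2, cc$resno2, cc$insert2, cc$atom2, sep = "|")
    swap <- k1 > k2
    tmp <- cc[swap, c("chain2", "resno2", "insert2", "atom2")]
    cc[swap, c("chain2", "resno2", "insert2", "atom2")] <-
      cc[swap, c("chain1", "resno1", "insert1", "atom1")]
    cc[swap, c("chain1", "resno1", "insert1", "atom1")] <- tmp
    cc <- cc[!duplicated(paste(pmin(k1, k2), pmax(k1, k2))), , drop = FALSE]
    rownames(cc) <- NULL
  }
  structure(list(rsrz = rsrz, close_contacts = cc), class = "nos_validation")
}

# RSRZ lookup keyed by chain/resno/insert; NA when the residue is absent.
rsrz_lookup <- function(val, chain, resno, insert = "") {
  key <- paste(val$rsrz$chain, val$rsrz$resno, val$rsrz$insert, sep = "|")
  q <- paste(chain, resno, insert, sep = "|")
  val$rsrz$rsrz[match(q, key)]
}
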