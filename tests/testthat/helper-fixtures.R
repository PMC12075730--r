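# Shared fixture builders (everything is generated in code at test time).

write_entry_files <- function(spec, dir = tempfile()) {
  files <- make_contact_structure(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(files$mmcif, file.path(dir, "structure.cif"))
  writeLines(files$bdb, file.path(dir, "bdb.pdb"))
  writeLines(files$validation, file.path(dir, "validation.xml"))
  list(dir = dir, files = files)
}

read_entry <- function(dir) {
  list(structure = read_structure(file.path(dir, "structure.cif")),
       bdb = read_bdb_bfactors(file.path(dir, "bdb.pdb")),
       validation = read_validation_report(file.path(dir, "validation.xml")))
}

# screen one spec end to end; returns retained/rejected pair tables
screen_spec <- function(spec, cfg = screening_config()) {
  e <- read_entry(write_entry_files(spec)$dir)
  pairs <- select_target_classes(find_sn_contacts(e$structure, cfg), cfg)
  apply_quality_filters(pairs, e$structure, e$bdb, e$validation, cfg)
}

# a small random structure mixing donors, acceptors and bystander atoms,
# used by the brute-force contact-oracle comparison
random_contact_structure <- function(n_atoms = 50, seed = 1, box = 8) {
  set.seed(seed)
  kinds <- list(
    list(atom = "SG", element = "S", resid = "CYS"),
    list(atom = "SD", element = "S", resid = "MET"),
    list(atom = "N", element = "N", resid = "GLY"),
    list(atom = "NZ", element = "N", resid = "LYS"),
    list(atom = "NH1", element = "N", resid = "ARG"),
    list(atom = "CA", element = "C", resid = "ALA"),
    list(atom = "O", element = "O", resid = "SER")
  )
  pick <- sample(seq_along(kinds), n_atoms, replace = TRUE)
  atoms <- do.call(rbind, lapply(seq_len(n_atoms), function(i) {
    k <- kinds[[pick[i]]]
    data.frame(atom = k$atom, element = k$element, resid = k$resid,
               chain = "A", resno = i, insert = "", alt = "",
               x = runif(1, 0, box), y = runif(1, 0, box), z = runif(1, 0, box),
               o = 1, b = 10, stringsAsFactors = FALSE)
  }))
  nos_structure(atoms, pdb_id = "rand", method = "xray", resolution = 1.5)
}
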