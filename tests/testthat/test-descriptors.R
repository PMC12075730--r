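# Geometry, SASA, packing counts and descriptor assembly.

simple_structure <- function(atoms) {
  nos_structure(atoms, method = "xray", resolution = 1.5)
}

test_that("nearest bonded carbon follows covalent distance", {
  e <- read_entry(write_entry_files(contact_spec())$dir)
  s <- e$structure
  # Cys SG -> CB (the only carbon within 1.9 A)
  i <- nearest_bonded_carbon(s, "A", 10, "", "SG")
  expect_identical(s$atoms$atom[i], "CB")
  # backbone N -> preceding residue's carbonyl C (1.33 A beats CA's 1.46 A)
  j <- nearest_bonded_carbon(s, "A", 2, "", "N")
  expect_identical(s$atoms$atom[j], "C")
  expect_identical(s$atoms$resno[j], 1L)
  # Arg NH1 -> CZ
  ea <- read_entry(write_entry_files(contact_spec(partner = "ARG"))$dir)
  k <- nearest_bonded_carbon(ea$structure, "A", 2, "", "NH1")
  expect_identical(ea$structure$atoms$atom[k], "CZ")
  # isolated nitrogen: no carbon in covalent range -> failure signal
  iso <- simple_structure(data.frame(
    atom = c("N", "CA"), element = c("N", "C"), resid = "GLY", chain = "A",
    resno = 1L, insert = "", alt = "", x = c(0, 5), y = 0, z = 0,
    o = 1, b = 10, stringsAsFactors = FALSE))
  expect_true(is.na(nearest_bonded_carbon(iso, "A", 1, "", "N")))
})

test_that("orthogonal and planar placements give textbook geometry", {
  atoms <- data.frame(
    atom = c("CB", "SG", "N", "C", "CA"), element = c("C", "S", "N", "C", "C"),
    resid = c("CYS", "CYS", "GLY", "GLY", "GLY"), chain = "A",
    resno = c(10L, 10L, 2L, 2L, 2L), insert = "", alt = "",
    x = c(1.8, 0, 0, -1.2, -2.2), y = c(0, 0, 2.7, 3.4, 3.4), z = 0,
    o = 1, b = 10, stringsAsFactors = FALSE
  )
  s <- simple_structure(atoms)
  pair <- data.frame(chain_s = "A", resno_s = 10L, insert_s = "", atom_s = "SG",
                     chain_n = "A", resno_n = 2L, insert_n = "", atom_n = "N",
                     stringsAsFactors = FALSE)
  g <- compute_geometry(s, pair)
  expect_equal(unname(g["angle_csn"]), 90, tolerance = 1e-9)
  expect_equal(unname(g["dist_sn"]), 2.7, tolerance = 1e-9)
  # all four atoms coplanar (z = 0), C and CB on opposite sides -> trans
  expect_equal(abs(unname(g["torsion_cs_nc"])), 180, tolerance = 1e-6)
})

test_that("geometry matches the direct vector-algebra oracle on 1000 configs", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    # reject near-degenerate configurations the geometry precondition excludes
    if (min(dist(pts)) < 0.5) next
    atoms <- data.frame(
      atom = c("CB", "SG", "N", "C", "CA"),
      element = c("C", "S", "N", "C", "C"),
      resid = c("CYS", "CYS", "GLY", "GLY", "GLY"), chain = "A",
      resno = c(10L, 10L, 2L, 2L, 2L), insert = "", alt = "",
      x = c(pts[1, 1], pts[2, 1], pts[3, 1], pts[4, 1], pts[3, 1] + 9),
      y = c(pts[1, 2], pts[2, 2], pts[3, 2], pts[4, 2], pts[3, 2]),
      z = c(pts[1, 3], pts[2, 3], pts[3, 3], pts[4, 3], pts[3, 3]),
      o = 1, b = 10, stringsAsFactors = FALSE
    )
    if (sqrt(sum((pts[1, ] - pts[2, ])^2)) > 1.9 ||
        sqrt(sum((pts[3, ] - pts[4, ])^2)) > 1.9) next
    s <- simple_structure(atoms)
    pair <- data.frame(chain_s = "A", resno_s = 10L, insert_s = "",
                       atom_s = "SG", chain_n = "A", resno_n = 2L,
                       insert_n = "", atom_n = "N", stringsAsFactors = FALSE)
    g <- compute_geometry(s, pair)
    o <- oracle_geometry(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    worst <- max(worst, max(abs(g - o[names(g)])))
  }
  expect_lt(worst, 1e-6)
})

test_that("geometry is rigid-motion invariant and torsion flips under mirror", {
  e <- read_entry(write_entry_files(contact_spec(torsion = 75))$dir)
  s <- e$structure
  pair <- find_sn_contacts(s)[1, ]
  g0 <- compute_geometry(s, pair)

  theta <- 0.7; R <- matrix(c(cos(theta), -sin(theta), 0,
                              sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s_rot <- s
  s_rot$atoms$x <- xyz[, 1] + 11.3
  s_rot$atoms$y <- xyz[, 2] - 4.2
  s_rot$atoms$z <- xyz[, 3] + 0.5
  g1 <- compute_geometry(s_rot, pair)
  expect_equal(g1, g0, tolerance = 1e-6)

  s_mir <- s
  s_mir$atoms$z <- -s_mir$atoms$z
  g2 <- compute_geometry(s_mir, pair)
  expect_equal(unname(g2["torsion_cs_nc"]), -unname(g0["torsion_cs_nc"]),
               tolerance = 1e-6)
  expect_equal(unname(g2["angle_csn"]), unname(g0["angle_csn"]),
               tolerance = 1e-6)
})

test_that("SASA reproduces the analytic sphere and burial limits", {
  one <- simple_structure(data.frame(
    atom = "SG", element = "S", resid = "CYS", chain = "A", resno = 1L,
    insert = "", alt = "", x = 0, y = 0, z = 0, o = 1, b = 10,
    stringsAsFactors = FALSE))
  sa <- compute_sasa(one)
  expect_equal(sa$atom$sasa, 4 * pi * (1.80 + 1.4)^2, tolerance = 0.02)

  # atom enclosed by a shell of sulfurs -> zero accessibility
  sh <- nosscan:::sphere_points(60) * 2.0
  shell <- data.frame(
    atom = c("SG", sprintf("S%02d", 1:60)), element = "S",
    resid = c("CYS", rep("MET", 60)), chain = "A",
    resno = c(1L, 1L + seq_len(60)), insert = "", alt = "",
    x = c(0, sh[, 1]), y = c(0, sh[, 2]), z = c(0, sh[, 3]),
    o = 1, b = 10, stringsAsFactors = FALSE)
  sb <- compute_sasa(simple_structure(shell))
  expect_equal(sb$atom$sasa[sb$atom$resno == 1], 0)

  # occlusion: two atoms expose strictly less than two isolated spheres
  two <- simple_structure(data.frame(
    atom = c("SG", "SD"), element = "S", resid = c("CYS", "MET"),
    chain = "A", resno = c(1L, 2L), insert = "", alt = "",
    x = c(0, 3.0), y = 0, z = 0, o = 1, b = 10, stringsAsFactors = FALSE))
  st <- compute_sasa(two)
  expect_lt(sum(st$atom$sasa), 2 * 4 * pi * (1.80 + 1.4)^2)

  # per-residue SASA is exactly the sum over member atoms
  e <- read_entry(write_entry_files(contact_spec())$dir)
  sfull <- compute_sasa(e$structure)
  at <- sfull$atom
  res_sums <- tapply(at$sasa, paste(at$chain, at$resno, at$insert), sum)
  for (i in seq_len(nrow(sfull$residue))) {
    key <- paste(sfull$residue$chain[i], sfull$residue$resno[i],
                 sfull$residue$insert[i])
    expect_identical(sfull$residue$sasa[i], unname(res_sums[key]))
  }
})

test_that("SASA decreases weakly as a second atom approaches", {
  prev <- Inf
  for (d in seq(7, 3, by = -0.5)) {
    two <- simple_structure(data.frame(
      atom = c("SG", "SD"), element = "S", resid = c("CYS", "MET"),
      chain = "A", resno = c(1L, 2L), insert = "", alt = "",
      x = c(0, d), y = 0, z = 0, o = 1, b = 10, stringsAsFactors = FALSE))
    now <- compute_sasa(two)$atom$sasa[1]
    expect_lte(now, prev + 1e-9)
    prev <- now
  }
})

test_that("neighbour counts count distinct residues, inclusively, once each", {
  base <- data.frame(
    atom = c("CA", "CB"), element = "C", resid = "CYS", chain = "A",
    resno = 1L, insert = "", alt = "", x = c(0, 1.5), y = 0, z = 0,
    o = 1, b = 10, stringsAsFactors = FALSE)
  expect_equal(count_neighbors(simple_structure(base), "A", 1, ""), 0L)

  for (k in c(1L, 3L, 7L, 20L)) {
    extra <- do.call(rbind, lapply(seq_len(k), function(i) {
      u <- nosscan:::sphere_points(k)[i, ] * 3.5
      data.frame(atom = "O", element = "O", resid = "SER", chain = "B",
                 resno = i, insert = "", alt = "", x = u[1], y = u[2],
                 z = u[3], o = 1, b = 10, stringsAsFactors = FALSE)
    }))
    s <- simple_structure(rbind(base, extra))
    expect_equal(count_neighbors(s, "A", 1, ""), k)
  }

  # two atoms of the same residue in range count once
  twice <- rbind(base,
                 data.frame(atom = c("O", "C"), element = c("O", "C"),
                            resid = "SER", chain = "B", resno = 1L,
                            insert = "", alt = "", x = c(2.0, 2.5), y = 0,
                            z = 0, o = 1, b = 10, stringsAsFactors = FALSE))
  expect_equal(count_neighbors(simple_structure(twice), "A", 1, ""), 1L)

  # missing C-alpha -> failure signal
  noca <- simple_structure(data.frame(
    atom = "CB", element = "C", resid = "CYS", chain = "A", resno = 1L,
    insert = "", alt = "", x = 0, y = 0, z = 0, o = 1, b = 10,
    stringsAsFactors = FALSE))
  expect_true(is.na(count_neighbors(noca, "A", 1, "")))
})

test_that("descriptor assembly yields 15 numeric fields and round-trips", {
  qf <- screen_spec(contact_spec(pdb_id = "asm1"))
  e <- read_entry(write_entry_files(contact_spec(pdb_id = "asm1"))$dir)
  d <- compute_descriptors(e$structure, qf$retained)
  expect_equal(nrow(d), 1)
  expect_identical(nos_descriptor_names(),
                   setdiff(names(d), nosscan:::nos_id_columns()))
  expect_length(nos_descriptor_names(), 15)
  expect_true(all(vapply(d[nos_descriptor_names()], is.numeric, logical(1))))
  expect_match(d$candidate_id, "asm1/")

  f <- tempfile(fileext = ".tsv")
  write_descriptor_tsv(d, f)
  d2 <- read_descriptor_tsv(f)
  expect_identical(d2[nos_descriptor_names()], d[nos_descriptor_names()])
  expect_identical(d2$candidate_id, d$candidate_id)
})

test_that("planted geometry is recovered to 1e-3 through file round trip", {
  qf <- screen_spec(contact_spec(dist_sn = 2.70, angle_csn = 94.02,
                                 angle_cns = 95.11, torsion = -120))
  e <- read_entry(write_entry_files(contact_spec(dist_sn = 2.70,
                                                 angle_csn = 94.02,
                                                 angle_cns = 95.11,
                                                 torsion = -120))$dir)
  d <- compute_descriptors(e$structure, qf$retained)
  expect_equal(d$dist_sn, 2.70, tolerance = 1e-3)
  expect_equal(d$angle_csn, 94.02, tolerance = 1e-3)
  expect_equal(d$angle_cns, 95.11, tolerance = 1e-3)
  expect_equal(d$torsion_cs_nc, -120, tolerance = 1e-3)
})
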