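# Independent oracles used to cross-check pipeline computations.

# Direct vector-algebra geometry, written independently of the package:
# angles via acos, torsion via the atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3))
# identity for the IUPAC-signed dihedral.
oracle_geometry <- function(CS, S, N, CN) {
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  crs <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                          u[3] * v[1] - u[1] * v[3],
                          u[1] * v[2] - u[2] * v[1])
  b1 <- S - CS; b2 <- N - S; b3 <- CN - N
  tors <- atan2(sqrt(sum(b2^2)) * sum(b1 * crs(b2, b3)),
                sum(crs(b1, b2) * crs(b2, b3))) * 180 / pi
  c(angle_csn = ang(CS - S, N - S),
    angle_cns = ang(CN - N, S - N),
    torsion_cs_nc = tors,
    dist_cn = sqrt(sum((N - CS)^2)),
    dist_sn = sqrt(sum((N - S)^2)))
}

# Textbook silhouette: per-point (b - a) / max(a, b) with explicit loops.
oracle_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force all-pairs S-N contact scan with the same donor/acceptor
# definitions, written as nested loops over raw atom rows.
oracle_sn_contacts <- function(s, cfg) {
  at <- s$atoms
  donors <- list(CYS = "SG", MET = "SD")
  side_n <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"), TRP = "NE1", ASN = "ND2", GLN = "NE2")
  std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  hits <- character(0)
  for (i in seq_len(nrow(at))) {
    for (j in seq_len(nrow(at))) {
      ri <- at$resid[i]
      if (!(ri %in% names(donors)) || at$atom[i] != donors[[ri]]) next
      rj <- at$resid[j]
      is_n <- (rj %in% std && at$atom[j] == "N") ||
        (rj %in% names(side_n) && at$atom[j] %in% side_n[[rj]])
      if (!is_n) next
      same <- at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j] &&
        at$insert[i] == at$insert[j] && at$resid[i] == at$resid[j]
      if (same) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d <= cfg$max_sn_dist + cfg$dist_epsilon)
        hits <- c(hits, paste(at$chain[i], at$resno[i], at$atom[i],
                              at$chain[j], at$resno[j], at$atom[j], sep = "|"))
    }
  }
  sort(hits)
}
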