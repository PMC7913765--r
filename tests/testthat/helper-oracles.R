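# Independent oracles and fixture builders used across the test files.

# Brute-force superposition oracle: coarse search over ZYZ Euler angles
# followed by local refinement; translation handled by centring. Independent
# of the SVD route used by kabschFit.
bruteForceRmsd <- function(moving, reference, gridStep = 12) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(reference, 2, colMeans(reference))
  eulerRot <- function(a, b, g) {
    rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    rz(a) %*% ry(b) %*% rz(g)
  }
  obj <- function(ang) {
    R <- eulerRot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  gs <- gridStep * pi / 180
  best <- NULL; bestV <- Inf
  for (a in seq(0, 2 * pi - gs / 2, by = gs))
    for (b in seq(0, pi, by = gs))
      for (g in seq(0, 2 * pi - gs / 2, by = gs)) {
        v <- obj(c(a, b, g))
        if (v < bestV) { bestV <- v; best <- c(a, b, g) }
      }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# hand-written 3-atom PDB fixture
writeTinyPdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# fixture with two alternate locations A/B for one CA atom
writeAltlocPdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.100   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# synthetic purine nucleoside fragment with a prescribed glycosidic chi,
# built directly from the O4'-C1'-N9-C4 convention (placement independent of
# dihedralAngle): O4' at a 60-degree elbow, C1'->N9 along z, C4 placed at
# azimuth chi from the O4' reference half-plane
writeNucleosidePdb <- function(path, chi, chains = "A", rigid = NULL) {
  lines <- character()
  serial <- 0
  for (i in seq_along(chains)) {
    p <- rbind("O4'" = c(1, 0, -1),
               "C1'" = c(0, 0, 0),
               "N9"  = c(0, 0, 1.47),
               "C4"  = c(1.37 * cos(chi[i] * pi / 180),
                         1.37 * sin(chi[i] * pi / 180), 2.2))
    if (!is.null(rigid))
      p <- sweep(p %*% t(rigid$R), 2, rigid$shift, `+`)
    for (j in seq_len(4)) {
      serial <- serial + 1
      nm <- rownames(p)[j]
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s EB4 %1s 401    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nm, chains[i], p[j, 1], p[j, 2], p[j, 3],
        substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# expected chi of the fixture above, via the package-independent standard
# formula (numeric cross/dot evaluation, duplicated on purpose)
referenceDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  atan2(sum(pracma::cross(n1, n2) * b2 / sqrt(sum(b2^2))),
        sum(n1 * n2)) * 180 / pi
}

# shift-table TSV fixture writer
writeShiftTsv <- function(path, resno, code, dH, dN) {
  writeLines(c("resno\tcode\tdH\tdN",
               sprintf("%d\t%s\t%.4f\t%.4f", resno, code, dH, dN)), path)
  path
}

# equivalent NMR-STAR chemical-shift loop fixture
writeShiftStar <- function(path, resno, code3, dH, dN) {
  hdr <- c("data_test", "", "save_assigned_chemical_shifts", "   loop_",
           "      _Atom_chem_shift.ID",
           "      _Atom_chem_shift.Comp_index_ID",
           "      _Atom_chem_shift.Comp_ID",
           "      _Atom_chem_shift.Atom_ID",
           "      _Atom_chem_shift.Val")
  rows <- character()
  id <- 0
  for (i in seq_along(resno)) {
    id <- id + 1
    rows <- c(rows, sprintf("      %d %d %s H %.4f", id, resno[i],
                            code3[i], dH[i]))
    id <- id + 1
    rows <- c(rows, sprintf("      %d %d %s N %.4f", id, resno[i],
                            code3[i], dN[i]))
  }
  writeLines(c(hdr, rows, "   stop_", "save_"), path)
  path
}
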