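test_that("a hand-written PDB round-trips through readStructure", {
  f <- writeTinyPdb(tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  a <- atoms(m)
  expect_equal(nrow(a), 3L)
  expect_equal(unique(a$chain), "A")
  expect_equal(unique(a$resno), 1L)
  expect_equal(a$name, c("N", "CA", "C"))
  expect_equal(a$x, c(0, 1.458, 2.009), tolerance = 1e-9)
})

test_that("alternate locations are retained on read and resolved on selection", {
  f <- writeAltlocPdb(tempfile(fileext = ".pdb"))
  m <- readStructure(f)
  a <- atoms(m)
  expect_equal(nrow(a), 4L)                       # both altlocs kept
  expect_setequal(a$alt[a$name == "CA"], c("A", "B"))
  r <- resolveAtoms(m, atomSelection("one", list(c(1, 1))), chain = "A")
  expect_equal(nrow(r), 3L)                       # N, CA, C once each
  expect_true(all(r$present))
  # altloc A kept (design rule), not the lower-occupancy B
  expect_equal(r$x[r$name == "CA"], 1.458, tolerance = 1e-9)
})

test_that("unreadable and empty files raise format errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb record", bad)
  expect_error(readStructure(bad))
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readStructure(empty))
})

test_that("built-in selections resolve to the expected backbone atom counts", {
  pair <- makeTwoDomainPair(124, 230, hingeAngle = 0, seed = 1)
  hd <- resolveAtoms(pair$reference, builtinSelection("HD"))
  # 3 backbone atoms x (56 + 14 + 30) residues
  expect_equal(sum(hd$present), 300L)
  art <- resolveAtoms(pair$reference, builtinSelection("ART"))
  # 3 x (147 + 71) residues
  expect_equal(sum(art$present), 3L * 218L)
  cat <- resolveAtoms(pair$reference, builtinSelection("CAT"))
  expect_equal(sum(cat$present), 300L + 654L)
})

test_that("missing residues are masked absent, never silently skipped", {
  pair <- makeTwoDomainPair(124, 230, hingeAngle = 0, seed = 1)
  a <- atoms(pair$reference)
  gap <- new("StructureModel", id = "gap",
             atoms = a[!(a$resno %in% 723:725), ])
  sel <- atomSelection("span", list(c(720, 728)))
  r <- resolveAtoms(gap, sel)
  expect_equal(nrow(r), 27L)                      # grid is complete
  expect_false(any(r$present[r$resno %in% 723:725]))
  expect_true(all(r$present[!r$resno %in% 723:725]))
  expect_error(resolveAtoms(gap, atomSelection("none", list(c(723, 725)))),
               "zero atoms")
})

test_that("selection grammar parses chain, range and atom fields", {
  sel <- parseSelection("A:666-721:N,CA,C; A:730-743")
  expect_s4_class(sel, "AtomSelection")
  expect_equal(nrow(sel@items), 2L)
  expect_equal(sel@items$chain, c("A", "A"))
  expect_equal(sel@items$atoms[2], "N,CA,C")      # default backbone
  expect_error(parseSelection("A:666-721; A:700-750"), "overlap")
  expect_error(parseSelection(""), "empty")
})

test_that("kabschFit recovers an applied rigid transform exactly", {
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  R <- rotationMatrix(c(1, -2, 0.5), 23)
  tr <- c(3, -1, 2)
  y <- sweep(x %*% t(R), 2, tr, `+`)
  f <- kabschFit(x, y)
  expect_lt(f@rmsdFit, 1e-9)
  expect_equal(f@rotation, R, tolerance = 1e-9)
  expect_equal(f@translation, tr, tolerance = 1e-9)
  expect_equal(det(f@rotation), 1, tolerance = 1e-9)
})

test_that("kabschFit matches the brute-force rotation-grid oracle", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    x <- matrix(rnorm(3 * n), n, 3)
    y <- sweep(x %*% t(rotationMatrix(rnorm(3), runif(1, 5, 40))), 2,
               rnorm(3), `+`) + matrix(rnorm(3 * n, 0, 0.3), n, 3)
    expect_equal(kabschFit(x, y)@rmsdFit, bruteForceRmsd(x, y),
                 tolerance = 1e-3)
  }
})

test_that("kabschFit rmsd is invariant under rigid motion of either input", {
  set.seed(31)
  x <- matrix(rnorm(24), 8, 3)
  y <- x + matrix(rnorm(24, 0, 0.5), 8, 3)
  base <- kabschFit(x, y)@rmsdFit
  for (rep in 1:3) {
    R <- rotationMatrix(rnorm(3), runif(1, 0, 180)); tr <- rnorm(3, 0, 10)
    expect_equal(kabschFit(sweep(x %*% t(R), 2, tr, `+`), y)@rmsdFit, base,
                 tolerance = 1e-9)
    expect_equal(kabschFit(x, sweep(y %*% t(R), 2, tr, `+`))@rmsdFit, base,
                 tolerance = 1e-9)
  }
})

test_that("kabschFit rejects degenerate input and never returns a reflection", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschFit(line, line + 1), "collinear")
  expect_error(kabschFit(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  # mirror-image cloud: optimum would be a reflection; result must stay proper
  set.seed(41)
  x <- matrix(rnorm(15), 5, 3)
  y <- x; y[, 1] <- -y[, 1]
  f <- kabschFit(x, y)
  expect_equal(det(f@rotation), 1, tolerance = 1e-9)
  expect_gt(f@rmsdFit, 0)
})

test_that("twoSetRmsd is zero on self-comparison and reduces to conventional rmsd", {
  pair <- makeTwoDomainPair(60, 60, hingeAngle = 12, kinkAngle = 5, seed = 3)
  selF <- pair$fixedSelection; selM <- pair$mobileSelection
  self <- twoSetRmsd(pair$reference, pair$reference, selF, selM)
  expect_lt(self@rmsdMeasure, 1e-9)
  s <- twoSetRmsd(pair$reference, pair$displaced, selF, selF)
  conv <- {
    ra <- resolveAtoms(pair$reference, selF)
    rb <- resolveAtoms(pair$displaced, selF)
    kabschFit(as.matrix(rb[, c("x", "y", "z")]),
              as.matrix(ra[, c("x", "y", "z")]))@rmsdFit
  }
  expect_equal(s@rmsdMeasure, conv, tolerance = 1e-9)
  expect_equal(s@rmsdFit, conv, tolerance = 1e-9)
})

test_that("cross-set rmsd equals the analytic displacement of the moved set", {
  pair <- makeTwoDomainPair(124, 230, hingeAngle = 10, seed = 7)
  s <- twoSetRmsd(pair$reference, pair$displaced,
                  fitSel = pair$fixedSelection,
                  measureSel = pair$mobileSelection)
  tru <- pair$truth@params$hinge
  a <- atoms(pair$reference)
  mob <- a$resno %in% pair$truth@params$mobileResidues
  xyz <- as.matrix(a[mob, c("x", "y", "z")])
  moved <- sweep(sweep(xyz, 2, tru$centre) %*% t(tru$rotation), 2,
                 tru$centre, `+`)
  analytic <- sqrt(mean(rowSums((moved - xyz)^2)))
  expect_equal(s@rmsdMeasure, analytic, tolerance = 1e-9)
  expect_lt(s@rmsdFit, 1e-9)       # fixed subdomain superposes exactly
})

test_that("twoSetRmsd pairs only the intersection and reports counts", {
  pair <- makeTwoDomainPair(60, 60, hingeAngle = 5, seed = 9)
  a <- atoms(pair$displaced)
  # remove three residues from the moving model's fixed subdomain
  dropRes <- pair$truth@params$fixedResidues[10:12]
  gapped <- new("StructureModel", id = "gap",
                atoms = a[!(a$resno %in% dropRes), ])
  s <- twoSetRmsd(pair$reference, gapped, pair$fixedSelection,
                  pair$mobileSelection)
  expect_equal(s@nFit, 3L * (60L - 3L))
  expect_equal(s@nMeasure, 3L * 60L)
  empty <- atomSelection("nowhere", list(c(5000, 5100)))
  expect_error(twoSetRmsd(pair$reference, gapped, empty,
                          pair$mobileSelection), "zero atoms")
})

test_that("caDistance computes Euclidean CA-CA distances", {
  at <- data.frame(chain = "A", resno = c(1L, 2L), resname = "ALA",
                   name = "CA", element = "C",
                   x = c(0, 3), y = c(0, 4), z = c(0, 0),
                   occ = 1, alt = "", stringsAsFactors = FALSE)
  m <- new("StructureModel", id = "toy", atoms = at)
  expect_equal(caDistance(m, "A", 1, 2), 5)
  expect_equal(caDistance(m, "A", 1, 1), 0)
  expect_error(caDistance(m, "A", 1, 3), "residue 3")
})

test_that("dihedralAngle obeys the sign convention and its symmetries", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.5)
  expect_equal(dihedralAngle(p1, p2, p3, c(1, 0, 1.5)), 0)      # cis
  expect_equal(dihedralAngle(p1, p2, p3, c(-1, 0, 1.5)), 180)   # trans
  th <- 60 * pi / 180
  stag <- c(cos(th), sin(th), 1.5)
  expect_equal(dihedralAngle(p1, p2, p3, stag), 60, tolerance = 1e-9)
  expect_equal(dihedralAngle(p1, p2, p3, stag),
               referenceDihedral(p1, p2, p3, stag), tolerance = 1e-9)
  # invariant under reversal of the point order (the IUPAC torsion reads
  # the same from either chain direction) but antisymmetric under
  # reflection; invariant under rigid motion
  set.seed(5)
  for (rep in 1:5) {
    p <- matrix(rnorm(12, 0, 2), 4, 3)
    ang <- tryCatch(dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]),
                    error = function(e) NULL)
    if (is.null(ang)) next
    expect_equal(dihedralAngle(p[4, ], p[3, ], p[2, ], p[1, ]), ang,
                 tolerance = 1e-9)
    pm <- p; pm[, 1] <- -pm[, 1]     # mirror image flips the sign
    expect_equal(dihedralAngle(pm[1, ], pm[2, ], pm[3, ], pm[4, ]), -ang,
                 tolerance = 1e-9)
    R <- rotationMatrix(rnorm(3), runif(1, 0, 360)); tr <- rnorm(3)
    q <- sweep(p %*% t(R), 2, tr, `+`)
    expect_equal(dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]), ang,
                 tolerance = 1e-9)
  }
  expect_error(dihedralAngle(p1, p1, p3, stag), "degenerate")
})

test_that("glycosidicChi reads the O4'-C1'-N9-C4 torsion and averages circularly", {
  f <- writeNucleosidePdb(tempfile(fileext = ".pdb"), chi = -60)
  m <- readStructure(f)
  expect_equal(glycosidicChi(m, "EB4"), -60, tolerance = 1e-3)
  # rigid motion leaves chi unchanged
  R <- rotationMatrix(c(2, 1, -1), 77)
  f2 <- writeNucleosidePdb(tempfile(fileext = ".pdb"), chi = -60,
                           rigid = list(R = R, shift = c(5, -3, 8)))
  expect_equal(glycosidicChi(readStructure(f2), "EB4"), -60,
               tolerance = 1e-3)
  # circular mean across chains straddling the -180/180 seam
  f3 <- writeNucleosidePdb(tempfile(fileext = ".pdb"), chi = c(-170, 170),
                           chains = c("A", "B"))
  m3 <- readStructure(f3)
  expect_equal(glycosidicChi(m3, "EB4"), 180, tolerance = 1e-3)
  expect_equal(sort(unname(glycosidicChi(m3, "EB4", average = FALSE))),
               c(-170, 170), tolerance = 1e-3)
  expect_error(glycosidicChi(m, "XYZ"), "not found")
})

test_that("superposition reports round-trip through the TSV writer", {
  pair <- makeTwoDomainPair(30, 30, hingeAngle = 8, seed = 2)
  s <- twoSetRmsd(pair$reference, pair$displaced, pair$fixedSelection,
                  pair$mobileSelection)
  tab <- superpositionTable(list(displaced = s), fitSet = "fixed",
                            measureSet = "mobile")
  f <- tempfile(fileext = ".tsv")
  writeSuperpositionReport(tab, f)
  back <- read.delim(f)
  expect_equal(back$rmsd_measure, s@rmsdMeasure, tolerance = 1e-6)
  expect_equal(back$n_fit, s@nFit)
})
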