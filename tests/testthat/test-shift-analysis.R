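test_that("TSV shift tables read with proline auto-flagging", {
  f <- writeShiftTsv(tempfile(fileext = ".tsv"),
                     resno = c(700, 701, 702), code = c("A", "P", "G"),
                     dH = c(8.1, 8.2, 8.3), dN = c(118, 119, 120))
  tb <- readShiftTable(f, "tsv")
  d <- shifts(tb)
  expect_equal(nrow(d), 3L)
  expect_equal(d$status, c("assigned", "proline", "assigned"))
  expect_true(is.na(d$dH[d$status == "proline"]))  # proline shifts ignored
})

test_that("duplicate residues and missing shift columns are errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("resno\tcode\tdH\tdN", "700\tA\t8.1\t118", "700\tG\t8.2\t119"),
             f)
  expect_error(readShiftTable(f, "tsv"), "duplicate")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("resno\tcode\tdH", "700\tA\t8.1"), f2)
  expect_error(readShiftTable(f2, "tsv"), "15N")
})

test_that("Sparky and NMR-STAR dialects give tables identical to the TSV", {
  resno <- 700:709
  code <- c("G", "A", "L", "S", "V", "T", "E", "K", "A", "G")
  code3 <- c("GLY", "ALA", "LEU", "SER", "VAL", "THR", "GLU", "LYS",
             "ALA", "GLY")
  set.seed(8)
  dH <- round(runif(10, 7.5, 9.5), 4); dN <- round(runif(10, 108, 128), 4)
  ft <- writeShiftTsv(tempfile(fileext = ".tsv"), resno, code, dH, dN)
  fs <- tempfile(fileext = ".list")
  writeLines(c("Assignment  w1  w2",
               sprintf("%s%dN-H  %.4f  %.4f", code, resno, dN, dH)), fs)
  fn <- writeShiftStar(tempfile(fileext = ".str"), resno, code3, dH, dN)
  a <- shifts(readShiftTable(ft, "tsv"))
  b <- shifts(readShiftTable(fs, "sparky"))
  c3 <- shifts(readShiftTable(fn, "nmrstar"))
  for (col in c("resno", "code", "dH", "dN", "status")) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-9)
    expect_equal(c3[[col]], a[[col]], tolerance = 1e-9)
  }
})

test_that("out-of-window amide shifts warn but do not fail", {
  expect_warning(shiftTable("x", 1:2, c("A", "A"), c(8, 20), c(118, 118)),
                 "1H")
  expect_warning(shiftTable("x", 1:2, c("A", "A"), c(8, 8), c(118, 80)),
                 "15N")
})

test_that("computeCsp applies the weighted-difference formula", {
  a <- shiftTable("ref", 1:3, c("A", "A", "A"), c(8, 8, 8), c(118, 118, 118))
  b <- shiftTable("per", 1:3, c("A", "A", "A"), c(8, 8.1, 8),
                  c(118, 118.5, 118))
  prof <- computeCsp(a, b)
  d <- cspValues(prof)
  expect_equal(d$csp[1], 0)
  expect_equal(d$csp[2], sqrt(0.1^2 + 0.1^2), tolerance = 1e-9)  # 0.1414
  expect_equal(d$csp[3], 0)
  # identical tables: all zero
  expect_true(all(cspValues(computeCsp(a, a))$csp == 0))
})

test_that("computeCsp is symmetric and translation invariant", {
  pair <- makeShiftPair(40, site = 675, amplitude = 0.8, decayLength = 4,
                        seed = 12)
  p1 <- cspValues(computeCsp(pair$reference, pair$perturbed))
  p2 <- cspValues(computeCsp(pair$perturbed, pair$reference))
  expect_equal(p1$csp, p2$csp, tolerance = 1e-12)
  # common offset in each dimension cancels
  sa <- shifts(pair$reference); sb <- shifts(pair$perturbed)
  off <- function(s) shiftTable(paste0("o"), s$resno, s$code, s$dH + 0.37,
                                s$dN + 2.11, s$status)
  p3 <- cspValues(computeCsp(off(sa), off(sb)))
  expect_equal(p3$csp, p1$csp, tolerance = 1e-12)
})

test_that("equal-weight case: dN = 5 dH contributes equally", {
  a <- shiftTable("ref", 1L, "A", 8, 118)
  b <- shiftTable("per", 1L, "A", 8 + 0.1, 118 + 0.5)
  expect_equal(cspValues(computeCsp(a, b))$csp, sqrt(2) * 0.1,
               tolerance = 1e-12)
})

test_that("residues assigned in one condition get status, not zero", {
  a <- shiftTable("ref", 1:3, c("A", "A", "A"), c(8, 8, 8), c(118, 118, 118))
  b <- shiftTable("per", 1:3, c("A", "A", "A"), c(8, NA, 8), c(118, NA, 118))
  d <- cspValues(computeCsp(a, b))
  expect_true(is.na(d$csp[2]))
  expect_equal(d$status[2], "unassigned")
  onlyP <- shiftTable("p", 1:3, c("P", "P", "P"), rep(NA_real_, 3),
                      rep(NA_real_, 3))
  expect_error(computeCsp(a, onlyP), "no residue")
})

test_that("planted synthetic perturbations are recovered to machine precision", {
  pair <- makeShiftPair(80, site = 700, amplitude = 1.3, decayLength = 5,
                        seed = 4, pProline = 0.1)
  d <- cspValues(computeCsp(pair$reference, pair$perturbed))
  tr <- pair$truth@params$planted
  m <- merge(d, tr, by = "resno", suffixes = c("", ".true"))
  assigned <- m$status == "assigned"
  expect_gt(sum(assigned), 50)
  expect_lt(max(abs(m$csp[assigned] - m$csp.true[assigned])), 1e-12)
  # prolines excluded from CSP entirely
  expect_true(all(is.na(m$csp[m$status == "proline"])))
})

test_that("global normalisation shares CSP_max and truncates the colour ramp", {
  a <- shiftTable("ref", 1:4, rep("A", 4), rep(8, 4), rep(118, 4))
  mk <- function(d1) shiftTable("per", 1:4, rep("A", 4), 8 + d1, rep(118, 4))
  p1 <- computeCsp(a, mk(c(0, 0.1, 0.5, 1.0)))    # max 1.0
  p2 <- computeCsp(a, mk(c(0, 0.05, 0.2, 0.6)))   # max 0.6
  ns <- normaliseProfiles(list(p1, p2))
  expect_equal(ns[[1]]@cspMax, 1.0)
  expect_equal(ns[[2]]@cspMax, 1.0)               # shared global maximum
  expect_equal(ns[[1]]@threshold, 0.2)
  d1 <- cspValues(ns[[1]])
  expect_equal(d1$colour[2], 0.5)                 # 0.1 / 0.2
  expect_equal(d1$colour[3], 1.0)                 # above threshold saturates
  # value exactly at the threshold maps to colour 1.0
  p3 <- normaliseProfiles(list(computeCsp(a, mk(c(0, 0.2, 0.5, 1.0)))))[[1]]
  expect_equal(cspValues(p3)$colour[2], 1.0)
  # all-zero profiles leave the threshold undefined
  expect_error(normaliseProfiles(list(computeCsp(a, mk(rep(0, 4))))),
               "zero")
})

test_that("residue attribute export is deterministic and round-trips", {
  pair <- makeShiftPair(20, site = 665, amplitude = 0.9, decayLength = 3,
                        seed = 6, pProline = 0.15)
  prof <- normaliseProfiles(computeCsp(pair$reference, pair$perturbed))[[1]]
  f <- tempfile(fileext = ".tsv")
  exportResidueAttributes(prof, f)
  back <- read.delim(f)
  d <- cspValues(prof)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$resno, d$resno)               # deterministic order
  ok <- !is.na(d$csp)
  expect_equal(back$csp[ok], d$csp[ok], tolerance = 1e-12)
  expect_true(all(is.na(back$colour[d$status == "proline"])))
  # saturated residue appears as exactly 1
  sat <- which.max(d$csp)
  expect_equal(back$colour[sat], 1.0)
  # identical bytes on re-export
  f2 <- tempfile(fileext = ".tsv")
  exportResidueAttributes(prof, f2)
  expect_identical(readLines(f), readLines(f2))
})
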