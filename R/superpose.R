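#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the rmsd between two
#' paired coordinate sets (SVD solution; a reflection, when it would give a
#' lower residual, is replaced by the best proper rotation). The fitted
#' coordinates of the moving set are `rotation %*% x + translation`.
#'
#' @param moving n x 3 matrix of coordinates to be transformed.
#' @param reference n x 3 matrix of target coordinates, paired row-by-row.
#' @return a [SuperpositionResult-class] with `rmsdFit` the minimised rmsd
#'   over the pairs (`rmsdMeasure` is `NA`).
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' R <- rotationMatrix(c(0, 0, 1), 30)
#' y <- x %*% t(R)
#' kabschFit(x, y)@rmsdFit   # ~0
#' @export
kabschFit <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (ncol(moving) != 3L || ncol(reference) != 3L)
    stop("coordinate sets must be n x 3 matrices")
  n <- nrow(moving)
  if (n != nrow(reference)) stop("coordinate sets must be paired (equal length)")
  if (n < 3L) stop("at least 3 atom pairs are required")
  if (!all(is.finite(moving)) || !all(is.finite(reference)))
    stop("non-finite coordinates")
  cm <- colMeans(moving); cr <- colMeans(reference)
  P <- sweep(moving, 2, cm); Q <- sweep(reference, 2, cr)
  # collinear (rank < 2) point sets leave the rotation underdetermined
  if (sum(svd(P)$d > 1e-8 * max(1, max(abs(P)))) < 2L ||
      sum(svd(Q)$d > 1e-8 * max(1, max(abs(Q)))) < 2L)
    stop("degenerate (collinear) geometry: rotation is underdetermined")
  s <- svd(crossprod(P, Q))           # H = P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- as.numeric(cr - R %*% cm)
  fitted <- sweep(moving %*% t(R), 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  new("SuperpositionResult", rotation = R, translation = t,
      rmsdFit = rmsd, rmsdMeasure = NA_real_,
      nFit = n, nMeasure = NA_integer_)
}

#' Rotation matrix about an axis (degrees)
#'
#' @param axis length-3 axis vector (normalised internally).
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) rotationAboutAxis(axis, angle)

#' Apply a superposition transform to coordinates
#'
#' @param result a [SuperpositionResult-class].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(result, xyz) {
  sweep(as.matrix(xyz) %*% t(result@rotation), 2, result@translation, `+`)
}

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd_fit = %.3f A over %d atoms",
              object@rmsdFit, object@nFit))
  if (!is.na(object@rmsdMeasure))
    cat(sprintf("; rmsd_measure = %.3f A over %d atoms",
                object@rmsdMeasure, object@nMeasure))
  cat("\n")
})

# resolve a selection on two models and return the paired coordinate
# matrices over the intersection of the presence masks
pairSelection <- function(modelA, modelB, selection, chainA, chainB) {
  ra <- resolveAtoms(modelA, selection, chain = chainA)
  rb <- resolveAtoms(modelB, selection, chain = chainB)
  if (nrow(ra) != nrow(rb))
    stop("selection resolves to different atom grids on the two models")
  keep <- ra$present & rb$present
  list(a = as.matrix(ra[keep, c("x", "y", "z")]),
       b = as.matrix(rb[keep, c("x", "y", "z")]),
       n = sum(keep))
}

#' Two-atom-set (cross-fitted) rmsd between two structures
#'
#' Superposes `modelB` onto `modelA` using the atoms of `fitSel` (set 1)
#' only, then computes the rmsd over `measureSel` (set 2) with that
#' transform unchanged. With `fitSel = measureSel` this reduces to the
#' conventional rmsd. Fitting on one rigid subdomain while measuring over the
#' other quantifies their relative displacement rather than internal
#' differences. Pairing uses only atoms present in both structures (the
#' intersection of the resolution masks), and both paired counts are
#' reported alongside the rmsds.
#'
#' @param modelA reference [StructureModel-class] (kept fixed).
#' @param modelB moving [StructureModel-class].
#' @param fitSel [AtomSelection-class] used to compute the transform (set 1).
#' @param measureSel [AtomSelection-class] the rmsd is measured over (set 2);
#'   defaults to `fitSel`.
#' @param chainA,chainB chains used on each model (default `"A"`).
#' @return a [SuperpositionResult-class] with both `rmsdFit` and
#'   `rmsdMeasure` populated.
#' @examples
#' pair <- makeTwoDomainPair(30, 30, hingeAngle = 10, seed = 7)
#' twoSetRmsd(pair$reference, pair$displaced,
#'            fitSel = pair$fixedSelection, measureSel = pair$mobileSelection)
#' @export
twoSetRmsd <- function(modelA, modelB, fitSel, measureSel = fitSel,
                       chainA = "A", chainB = "A") {
  fit <- pairSelection(modelA, modelB, fitSel, chainA, chainB)
  if (fit$n == 0L)
    stop("empty paired intersection in fit set '", fitSel@name, "'")
  if (fit$n < 3L)
    stop("fewer than 3 paired atoms in fit set '", fitSel@name, "'")
  sup <- kabschFit(fit$b, fit$a)
  mea <- pairSelection(modelA, modelB, measureSel, chainA, chainB)
  if (mea$n == 0L)
    stop("empty paired intersection in measure set '", measureSel@name, "'")
  moved <- applyTransform(sup, mea$b)
  rmsdM <- sqrt(mean(rowSums((moved - mea$a)^2)))
  new("SuperpositionResult", rotation = sup@rotation,
      translation = sup@translation, rmsdFit = sup@rmsdFit,
      rmsdMeasure = rmsdM, nFit = fit$n, nMeasure = mea$n)
}

#' Distance between two residues' CA atoms
#'
#' @param model a [StructureModel-class].
#' @param chain chain id.
#' @param resI,resJ author residue numbers.
#' @return Euclidean distance in Angstrom.
#' @export
caDistance <- function(model, chain, resI, resJ) {
  a <- atoms(model)
  getCA <- function(r) {
    sub <- a[a$chain == chain & a$resno == r & a$name == "CA", , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no CA atom for residue ", r, " in chain ", chain)
    sub <- resolveAltloc(sub)
    as.numeric(sub[1L, c("x", "y", "z")])
  }
  sqrt(sum((getCA(resI) - getCA(resJ))^2))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, a clockwise rotation of
#' the p3-p4 bond relative to p1-p2 is positive. The cis arrangement gives 0,
#' trans gives 180.
#'
#' @param p1,p2,p3,p4 length-3 position vectors.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate geometry: collinear points leave the torsion undefined")
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(cr * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Glycosidic chi torsion of a purine nucleoside ligand
#'
#' chi is computed with the O4'-C1'-N9-C4 atom convention. When the ligand
#' occurs in several chains and `average = TRUE`, the circular mean of the
#' per-chain torsions is returned (arithmetic averaging of angles near the
#' -180/180 seam would be meaningless).
#'
#' @param model a [StructureModel-class].
#' @param resname ligand residue name as deposited.
#' @param chain restrict to one chain id, or `NULL` (default) for all chains
#'   containing the ligand.
#' @param average return the circular mean across chains (default `TRUE`);
#'   otherwise a named per-chain vector.
#' @return chi in degrees, in (-180, 180].
#' @export
glycosidicChi <- function(model, resname, chain = NULL, average = TRUE) {
  a <- atoms(model)
  lig <- a[a$resname == resname, , drop = FALSE]
  if (!is.null(chain)) lig <- lig[lig$chain %in% chain, , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand '", resname, "' not found")
  need <- c("O4'", "C1'", "N9", "C4")
  perChain <- vapply(split(lig, paste(lig$chain, lig$resno)), function(sub) {
    sub <- resolveAltloc(sub)
    idx <- match(need, sub$name)
    if (anyNA(idx))
      stop("ligand lacks chi-defining atoms: ",
           paste(need[is.na(idx)], collapse = ", "))
    p <- as.matrix(sub[idx, c("x", "y", "z")])
    dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
  }, numeric(1))
  if (average) circularMeanDeg(perChain) else perChain
}

#' Tabulate superposition results as a report row
#'
#' @param results named list of [SuperpositionResult-class] objects; names
#'   are used as structure labels.
#' @param chain,fitSet,measureSet labels recorded in the output columns.
#' @return data.frame with columns `structure`, `chain`, `fit_set`,
#'   `measure_set`, `n_fit`, `n_measure`, `rmsd_fit`, `rmsd_measure`.
#' @export
superpositionTable <- function(results, chain = "A",
                               fitSet = "", measureSet = "") {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(structure = nm, chain = chain, fit_set = fitSet,
               measure_set = measureSet, n_fit = r@nFit,
               n_measure = r@nMeasure, rmsd_fit = r@rmsdFit,
               rmsd_measure = r@rmsdMeasure, stringsAsFactors = FALSE)
  }))
}

#' Write a superposition report as tab-separated text
#'
#' @param table data.frame from [superpositionTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSuperpositionReport <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
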