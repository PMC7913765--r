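# Synthetic scenarios with recorded ground truth. Every generator is a pure
# function of (parameters, seed): same seed, same bytes.

# ideal-helix backbone: CA on a helix of given radius/rise/twist, N and C at
# fixed angular/axial offsets so residues are non-collinear rigid bodies
idealHelixBackbone <- function(resno, origin = c(0, 0, 0), rise = 1.5,
                               twistDeg = 100, radius = 2.3) {
  n <- length(resno)
  i <- seq_len(n) - 1L
  mk <- function(dAng, dZ, r) {
    th <- (i * twistDeg + dAng) * pi / 180
    cbind(x = r * cos(th) + origin[1],
          y = r * sin(th) + origin[2],
          z = i * rise + dZ + origin[3])
  }
  co <- rbind(mk(-35, -0.5, 1.9), mk(0, 0, radius), mk(35, 0.5, 2.0))
  ord <- as.vector(t(matrix(seq_len(3L * n), n, 3L)))  # N,CA,C per residue
  data.frame(chain = "A",
             resno = rep(resno, each = 3L),
             resname = "ALA",
             name = rep(c("N", "CA", "C"), n),
             element = rep(c("N", "C", "C"), n),
             x = co[ord, 1L], y = co[ord, 2L], z = co[ord, 3L],
             occ = 1, alt = "", stringsAsFactors = FALSE)
}

#' Synthetic two-subdomain structure pair with a known hinge displacement
#'
#' Builds two rigid poly-alanine helical subdomains joined at a hinge — a
#' geometric toy for the situation where one subdomain (HD-like, "mobile")
#' is displaced as a rigid body relative to the other (ART-like, "fixed").
#' The displaced copy applies a rotation of `hingeAngle` degrees about a
#' fixed axis through the hinge residue's CA to every mobile atom, and
#' optionally kinks the mobile helix by `kinkAngle` at its midpoint (the
#' analogue of a helix kinking at a buried acidic residue). The exact
#' transform is recorded in the returned truth, so the rmsd any downstream
#' superposition should report is computable analytically.
#'
#' Residue numbering starts at `firstRes` (default 656) so that with
#' `nResFixed = 124` and `nResMobile = 230` the built-in HD ranges fall in
#' the fixed subdomain and the ART ranges in the mobile one.
#'
#' @param nResFixed,nResMobile residue counts (>= 10 each).
#' @param hingeAngle,kinkAngle degrees, in \[0, 60\].
#' @param seed RNG seed (reserved for future noise options; the geometry is
#'   deterministic).
#' @param firstRes first residue number.
#' @return list with `reference` and `displaced` ([StructureModel-class]),
#'   `truth` ([SyntheticTruth-class]; `params$hinge` holds the rotation
#'   matrix, axis, angle and centre), and convenience [AtomSelection-class]
#'   objects `fixedSelection` / `mobileSelection`.
#' @export
makeTwoDomainPair <- function(nResFixed, nResMobile, hingeAngle,
                              kinkAngle = 0, seed = 1, firstRes = 656) {
  if (nResFixed < 10L || nResMobile < 10L)
    stop("subdomain residue counts must be at least 10")
  if (hingeAngle < 0 || hingeAngle > 60 || kinkAngle < 0 || kinkAngle > 60)
    stop("hinge and kink angles must lie in [0, 60] degrees")
  fixedRes <- firstRes:(firstRes + nResFixed - 1L)
  mobileRes <- (firstRes + nResFixed):(firstRes + nResFixed + nResMobile - 1L)
  fixed <- idealHelixBackbone(fixedRes)
  # mobile helix continues from the top of the fixed one, offset in x
  top <- max(fixed$z)
  mobile <- idealHelixBackbone(mobileRes, origin = c(9, 0, top + 3))
  ref <- rbind(fixed, mobile)
  hingeCA <- as.numeric(
    mobile[mobile$resno == mobileRes[1L] & mobile$name == "CA",
           c("x", "y", "z")])
  axis <- c(0, 1, 0)
  R <- rotationAboutAxis(axis, hingeAngle)
  disp <- ref
  mob <- disp$resno %in% mobileRes
  if (hingeAngle > 0)
    disp[mob, c("x", "y", "z")] <-
      applyRigid(as.matrix(ref[mob, c("x", "y", "z")]), R, centre = hingeCA)
  kink <- NULL
  if (kinkAngle > 0) {
    midRes <- fixedRes[ceiling(nResFixed / 2)]
    midCA <- as.numeric(
      fixed[fixed$resno == midRes & fixed$name == "CA", c("x", "y", "z")])
    Rk <- rotationAboutAxis(c(1, 0, 0), kinkAngle)
    tail <- disp$resno %in% fixedRes[fixedRes > midRes]
    disp[tail, c("x", "y", "z")] <-
      applyRigid(as.matrix(disp[tail, c("x", "y", "z")]), Rk, centre = midCA)
    kink <- list(angle = kinkAngle, axis = c(1, 0, 0), centre = midCA,
                 rotation = Rk, residues = fixedRes[fixedRes > midRes])
  }
  truth <- new("SyntheticTruth", scenario = "two_domain_hinge",
               params = list(
                 hinge = list(angle = hingeAngle, axis = axis,
                              centre = hingeCA, rotation = R),
                 kink = kink,
                 fixedResidues = fixedRes, mobileResidues = mobileRes),
               seed = as.integer(seed))
  list(reference = new("StructureModel", id = "synthetic-ref", atoms = ref),
       displaced = new("StructureModel", id = "synthetic-disp", atoms = disp),
       truth = truth,
       fixedSelection = atomSelection("fixed",
                                      list(range(fixedRes))),
       mobileSelection = atomSelection("mobile",
                                       list(range(mobileRes))))
}

#' Synthetic shift-table pair with a localised planted perturbation
#'
#' Base amide shifts are drawn uniformly in plausible windows (1H 7.5-9.5
#' ppm, 15N 105-130 ppm). The perturbed table adds to residue `r` a shift
#' vector of magnitude `amplitude * exp(-|r - site| / decayLength)` split at
#' a random angle between the 1H and (pre-scaled by 5) 15N dimensions, so
#' the planted CSP equals that magnitude exactly and
#' [computeCsp()] should recover it to machine precision.
#'
#' @param nRes number of residues.
#' @param site perturbation centre (residue number).
#' @param amplitude peak perturbation, ppm (>= 0).
#' @param decayLength exponential decay length in residues.
#' @param seed RNG seed.
#' @param firstRes first residue number (default 656).
#' @param pProline fraction of residues flagged proline (excluded from CSP).
#' @return list with `reference`, `perturbed` ([ShiftTable-class]) and
#'   `truth` (`params$planted`: data.frame of resno and planted CSP).
#' @export
makeShiftPair <- function(nRes, site, amplitude, decayLength = 3, seed = 1,
                          firstRes = 656, pProline = 0) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  resno <- firstRes:(firstRes + nRes - 1L)
  if (!site %in% resno)
    stop("perturbation site ", site, " outside residue range ",
         firstRes, "-", max(resno))
  withSeed(seed, {
    dH <- stats::runif(nRes, 7.5, 9.5)
    dN <- stats::runif(nRes, 105, 130)
    code <- sample(c("A", "G", "L", "S", "V", "T", "E", "K"), nRes,
                   replace = TRUE)
    if (pProline > 0) {
      nP <- max(0L, round(pProline * nRes))
      code[sample(nRes, nP)] <- "P"
    }
    planted <- amplitude * exp(-abs(resno - site) / decayLength)
    phi <- stats::runif(nRes, 0, 2 * pi)
    ref <- shiftTable("synthetic-ref", resno, code, dH, dN)
    per <- shiftTable("synthetic-perturbed", resno, code,
                      dH + planted * cos(phi),
                      dN + 5 * planted * sin(phi))
    planted[code == "P"] <- NA_real_
    truth <- new("SyntheticTruth", scenario = "shift_pair",
                 params = list(planted = data.frame(resno = resno,
                                                    csp = planted),
                               site = site, amplitude = amplitude,
                               decayLength = decayLength),
                 seed = as.integer(seed))
    list(reference = ref, perturbed = per, truth = truth)
  })
}

#' Synthetic mono-exponential relaxation decays
#'
#' `I(t) = exp(-t / T_true)` evaluated on a delay schedule (the T1 schedule
#' by default, duplicates preserved) plus homoscedastic Gaussian noise of
#' standard deviation `noiseSigma * I0`.
#'
#' @param tTrue true relaxation time, ms (> 0).
#' @param delays delay schedule in ms (default [delaySchedule()] for T1).
#' @param noiseSigma noise sd as a fraction of the t=0 amplitude.
#' @param nReplicates number of independent series.
#' @param seed RNG seed.
#' @param kind `"T1"` or `"T1rho"` tag on the series.
#' @return list with `series` (list of [RelaxationSeries-class], resno =
#'   replicate index) and `truth`.
#' @export
makeDecaySeries <- function(tTrue, delays = delaySchedule("T1"),
                            noiseSigma = 0, nReplicates = 1, seed = 1,
                            kind = "T1") {
  .assertScalarPositive(tTrue, "tTrue")
  withSeed(seed, {
    series <- lapply(seq_len(nReplicates), function(r) {
      y <- exp(-delays / tTrue) +
        if (noiseSigma > 0) stats::rnorm(length(delays), 0, noiseSigma) else 0
      relaxationSeries(r, kind, delays, y, noise = noiseSigma)
    })
    truth <- new("SyntheticTruth", scenario = "decay",
                 params = list(T = tTrue, noiseSigma = noiseSigma,
                               delays = delays),
                 seed = as.integer(seed))
    list(series = series, truth = truth)
  })
}

#' Synthetic exchange observables from per-residue first-order rates
#'
#' Real-time intensities are `exp(-k * t)` at the 3/12/39 h points (plus
#' optional Gaussian noise, floored at 0); a CLEANEX intensity is present iff
#' the rate lies inside the CLEANEX-detectable window. Ground-truth classes
#' are computed analytically from the rates via [simulateClassFromRate()]
#' and stored in the truth, so a downstream classifier can be scored without
#' re-deriving them.
#'
#' @param rates named numeric vector, names = residue numbers, values =
#'   exchange rates in /s (> 0).
#' @param times real-time points in hours.
#' @param cleanexWindow `(k_min, k_max)` in /s within which CLEANEX detects
#'   the residue (default `c(0.5, 100)`).
#' @param noiseSigma Gaussian noise sd on all intensities.
#' @param seed RNG seed.
#' @param threshold detection threshold (multiple of `noiseSigma`) used when
#'   deriving the ground-truth classes; keep equal to the threshold later
#'   passed to [classifyTable()] so that truth and classification share the
#'   same detection floor.
#' @return list with `table` (unclassified [ExchangeTable-class]) and
#'   `truth` (`params$classes`: named character vector).
#' @export
makeExchangeProfile <- function(rates, times = c(3, 12, 39),
                                cleanexWindow = c(0.5, 100),
                                noiseSigma = 0, seed = 1, threshold = 3) {
  if (any(rates <= 0)) stop("all exchange rates must be positive")
  if (is.null(names(rates))) names(rates) <- seq_along(rates)
  resno <- as.integer(names(rates))
  withSeed(seed, {
    noisy <- function(x) {
      if (noiseSigma > 0) x <- x + stats::rnorm(length(x), 0, noiseSigma)
      pmax(x, 0)
    }
    inWin <- rates >= cleanexWindow[1L] & rates <= cleanexWindow[2L]
    cl <- ifelse(inWin, 1, NA_real_)
    cl[inWin] <- noisy(cl[inWin])
    It <- vapply(times, function(tt) noisy(exp(-rates * 3600 * tt)),
                 numeric(length(rates)))
    d <- data.frame(resno = resno, cleanex = cl, reference = 1,
                    i3 = It[, 1L], i12 = It[, 2L], i39 = It[, 3L],
                    noise = noiseSigma, class = NA_character_,
                    stringsAsFactors = FALSE)
    # analytic ground truth from the rule set: CLEANEX-visible rates are
    # fast; otherwise the exact intensities decide the slow class under the
    # same detection floor a downstream classifier will apply, and a 3 h
    # point at/below the floor (including rates too fast for real time yet
    # above the CLEANEX window) is unobserved
    floorv <- threshold * noiseSigma
    classes <- vapply(seq_along(rates), function(i) {
      if (inWin[i]) return("fast")
      I <- exp(-rates[i] * 3600 * times)
      if (I[1L] <= floorv) return("unobserved")
      classifySlow(I[1L], ifelse(I[2L] > floorv, I[2L], 0),
                   ifelse(I[3L] > floorv, I[3L], 0))
    }, "")
    names(classes) <- resno
    truth <- new("SyntheticTruth", scenario = "exchange_profile",
                 params = list(rates = rates, classes = classes,
                               cleanexWindow = cleanexWindow,
                               noiseSigma = noiseSigma),
                 seed = as.integer(seed))
    list(table = new("ExchangeTable", data = d), truth = truth)
  })
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth '", object@scenario, "' (seed ", object@seed,
      "): parameters ", paste(names(object@params), collapse = ", "),
      "\n", sep = "")
})

#' Write a SyntheticTruth as a flat key-value manifest
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthManifest <- function(truth, path) {
  flat <- function(x, prefix = "") {
    if (is.list(x)) {
      unlist(lapply(names(x), function(nm)
        flat(x[[nm]], paste0(prefix, nm, "."))), use.names = FALSE)
    } else {
      vals <- paste(fmtNum(as.numeric(x)), collapse = ",")
      if (is.character(x)) vals <- paste(x, collapse = ",")
      paste0(sub("\\.$", "", prefix), " = ", vals)
    }
  }
  writeLines(c(paste0("scenario = ", truth@scenario),
               paste0("seed = ", truth@seed),
               flat(truth@params)), path)
  invisible(path)
}
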