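#' Chemical-shift perturbation between two sample conditions
#'
#' For every residue assigned in both tables the combined amide perturbation
#' is
#' \deqn{CSP = \sqrt{\Delta\delta(^1H)^2 + (\Delta\delta(^{15}N)/5)^2}}
#' (ppm). The 15N scaling divisor 5 reflects the relative shift dispersion of
#' the two nuclei and can be changed for other conventions. Residues not
#' assigned in both conditions carry a status instead of a value — scoring
#' them 0 would fabricate agreement between the conditions. The operation is
#' symmetric in its two arguments.
#'
#' @param reference,perturbed [ShiftTable-class] objects sharing a residue
#'   numbering frame.
#' @param nscale 15N scaling divisor (default 5).
#' @return a [CSPProfile-class]; `cspMax` and `threshold` are set from this
#'   profile alone until [normaliseProfiles()] imposes a global maximum.
#' @examples
#' pair <- makeShiftPair(50, site = 25, amplitude = 1, decayLength = 3, seed = 1)
#' prof <- computeCsp(pair$reference, pair$perturbed)
#' max(cspValues(prof)$csp, na.rm = TRUE)
#' @export
computeCsp <- function(reference, perturbed, nscale = 5) {
  stopifnot(is(reference, "ShiftTable"), is(perturbed, "ShiftTable"))
  .assertScalarPositive(nscale, "nscale")
  a <- shifts(reference); b <- shifts(perturbed)
  resno <- sort(union(a$resno, b$resno))
  ia <- match(resno, a$resno); ib <- match(resno, b$resno)
  sa <- a$status[ia]; sb <- b$status[ib]
  # status precedence for residues without a CSP: the loop annotation and
  # proline identity outrank plain unassigned
  status <- rep("unassigned", length(resno))
  both <- !is.na(sa) & !is.na(sb)
  status[both & sa == "assigned" & sb == "assigned"] <- "assigned"
  for (s in c("proline", "unobserved_loop")) {
    hit <- (!is.na(sa) & sa == s) | (!is.na(sb) & sb == s)
    status[hit] <- s
  }
  csp <- rep(NA_real_, length(resno))
  k <- status == "assigned"
  if (!any(k)) stop("no residue is assigned in both tables")
  csp[k] <- sqrt((a$dH[ia][k] - b$dH[ib][k])^2 +
                   ((a$dN[ia][k] - b$dN[ib][k]) / nscale)^2)
  cspMax <- max(csp, na.rm = TRUE)
  prof <- new("CSPProfile",
              label = paste(sampleLabel(reference), "vs",
                            sampleLabel(perturbed)),
              data = data.frame(resno = resno, csp = csp, status = status,
                                colour = NA_real_, stringsAsFactors = FALSE),
              cspMax = cspMax, threshold = 0.2 * cspMax, nscale = nscale)
  if (cspMax > 0) prof <- .applyColour(prof)
  prof
}

#' @describeIn CSPProfile-class per-residue CSP data accessor.
#' @param x a `CSPProfile`.
#' @export
cspValues <- function(x) x@data

#' @describeIn CSPProfile-class the colour-truncation threshold (ppm).
#' @export
cspThreshold <- function(x) x@threshold

setMethod("show", "CSPProfile", function(object) {
  d <- object@data
  cat(sprintf(
    "CSPProfile '%s': %d residues, %d with CSP, max %.4g ppm (threshold %.4g)\n",
    object@label, nrow(d), sum(!is.na(d$csp)), object@cspMax,
    object@threshold))
})

.applyColour <- function(profile) {
  d <- profile@data
  d$colour <- pmin(d$csp / profile@threshold, 1)
  profile@data <- d
  profile
}

#' Globally normalise a set of CSP profiles
#'
#' Imposes a single CSP_max (the largest CSP across all the profiles) so
#' that colour scales are comparable between samples. The colour ramp is
#' truncated: it runs from 0 to 0.2*CSP_max, and residues at or above that
#' threshold saturate at colour value 1 — without truncation the mapping
#' would be dominated by a few large, relatively uninformative perturbations
#' at the binding site.
#'
#' @param profiles a list of [CSPProfile-class] objects (a single profile
#'   may be passed bare).
#' @return the same list with shared `cspMax`, `threshold` and recomputed
#'   colour values.
#' @export
normaliseProfiles <- function(profiles) {
  if (is(profiles, "CSPProfile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, is, TRUE, "CSPProfile")))
    stop("profiles must be CSPProfile objects")
  allCsp <- unlist(lapply(profiles, function(p) p@data$csp))
  if (!any(is.finite(allCsp)))
    stop("no finite CSP values across the profiles")
  cspMax <- max(allCsp, na.rm = TRUE)
  if (cspMax <= 0)
    stop("all CSP values are zero: truncation threshold undefined")
  lapply(profiles, function(p) {
    p@cspMax <- cspMax
    p@threshold <- 0.2 * cspMax
    .applyColour(p)
  })
}

#' Export per-residue CSP attributes for a structure viewer
#'
#' Writes one tab-separated line per residue (residue number, raw CSP,
#' colour value, status) in residue order — the hand-off format for mapping
#' perturbations onto a structure. Residues without a CSP (prolines,
#' unassigned, unobserved loop) are emitted with their status tag and an
#' empty colour field.
#'
#' @param profile a [CSPProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportResidueAttributes <- function(profile, path) {
  d <- profile@data[order(profile@data$resno), ]
  lines <- sprintf("%d\t%s\t%s\t%s", d$resno,
                   ifelse(is.na(d$csp), "", fmtNum(d$csp)),
                   ifelse(is.na(d$colour), "", fmtNum(d$colour)),
                   d$status)
  writeLines(c("resno\tcsp\tcolour\tstatus", lines), path)
  invisible(path)
}
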