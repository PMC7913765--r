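#' @import methods
NULL

#' StructureModel: chains, residues and atoms of a deposited or synthetic model
#'
#' Thin container for an atomic model read from a PDB/mmCIF file or built by
#' the synthetic generators. Coordinates are orthogonal and in Angstrom;
#' residue numbering is the author numbering of the source file (no
#' renumbering). Alternate locations are retained on read and resolved only
#' when atoms are selected (see [resolveAtoms()]).
#'
#' @slot id text label, typically the PDB code.
#' @slot atoms data.frame with columns `chain`, `resno`, `resname`, `name`
#'   (atom name), `element`, `x`, `y`, `z`, `occ`, `alt` (alternate-location
#'   tag, `""` when unset).
#' @export
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame"),
  validity = function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "resname", "name", "element",
              "x", "y", "z", "occ", "alt")
    if (!all(need %in% names(a)))
      return(paste("atoms lacks columns:",
                   paste(setdiff(need, names(a)), collapse = ", ")))
    if (nrow(a) == 0L) return("empty model: no atoms")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    TRUE
  })

#' AtomSelection: a named, ordered set of (chain, residue-range, atom-name) items
#'
#' Defines which backbone atoms enter a superposition or an rmsd measurement.
#' The built-in CAT/HD/ART selections reproduce the subdomain definitions used
#' throughout the package (see [builtinSelection()]).
#'
#' @slot name text label.
#' @slot items data.frame with columns `chain` (NA = take the chain given at
#'   resolution time), `start`, `end` (inclusive author residue numbers) and
#'   `atoms` (comma-separated atom names).
#' @export
setClass("AtomSelection",
  representation(name = "character", items = "data.frame"),
  validity = function(object) {
    it <- object@items
    need <- c("chain", "start", "end", "atoms")
    if (!all(need %in% names(it)))
      return(paste("items lacks columns:",
                   paste(setdiff(need, names(it)), collapse = ", ")))
    if (nrow(it) == 0L) return("selection has no items")
    if (any(it$end < it$start)) return("range end precedes start")
    # ranges non-overlapping within a chain
    for (ch in unique(it$chain)) {
      sub <- it[is.na(it$chain) == is.na(ch) &
                  (is.na(ch) | it$chain %in% ch), , drop = FALSE]
      if (nrow(sub) > 1L) {
        o <- order(sub$start)
        if (any(sub$start[o][-1L] <= sub$end[o][-nrow(sub)]))
          return("residue ranges overlap within selection")
      }
    }
    TRUE
  })

#' SuperpositionResult: transform and rmsd values from a (two-set) superposition
#'
#' @slot rotation 3x3 proper rotation matrix (determinant +1).
#' @slot translation length-3 translation vector (Angstrom); the fitted
#'   coordinates are `rotation %*% x + translation`.
#' @slot rmsdFit rmsd over the fit set (set 1) after superposition, Angstrom.
#' @slot rmsdMeasure rmsd over the measure set (set 2) using the set-1
#'   transform unchanged; `NA` for a plain fit.
#' @slot nFit,nMeasure paired-atom counts actually used.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsdFit = "numeric", rmsdMeasure = "numeric",
                 nFit = "integer", nMeasure = "integer"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (abs(det(R) - 1) > 1e-6) return("rotation is not proper (det != +1)")
    if (length(object@translation) != 3L) return("translation must be length 3")
    if (!is.na(object@rmsdFit) && object@rmsdFit < 0) return("negative rmsd")
    TRUE
  })

#' ShiftTable: per-residue backbone amide chemical shifts for one sample
#'
#' @slot label sample condition label.
#' @slot data data.frame with columns `resno`, `code` (one-letter residue
#'   code), `dH` (ppm), `dN` (ppm), `status` one of `"assigned"`,
#'   `"proline"`, `"unassigned"` (overlapped/unassigned), `"unobserved_loop"`.
#' @export
setClass("ShiftTable",
  representation(label = "character", data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("resno", "code", "dH", "dN", "status")
    if (!all(need %in% names(d)))
      return(paste("data lacks columns:",
                   paste(setdiff(need, names(d)), collapse = ", ")))
    if (anyDuplicated(d$resno)) return("duplicate residue numbers")
    bad <- setdiff(unique(d$status), .shiftStatuses)
    if (length(bad)) return(paste("unknown status:", paste(bad, collapse = ",")))
    TRUE
  })

.shiftStatuses <- c("assigned", "proline", "unassigned", "unobserved_loop")

#' CSPProfile: per-residue chemical-shift perturbations with colour mapping
#'
#' @slot label comparison label (reference vs perturbed sample).
#' @slot data data.frame with columns `resno`, `csp` (ppm, `NA` where not
#'   computable), `status`, `colour` (normalised value in \[0,1\], `NA`
#'   until [normaliseProfiles()] is applied or for non-assigned residues).
#' @slot cspMax global maximum CSP (ppm) shared across the normalised set.
#' @slot threshold colour-truncation threshold, `0.2 * cspMax` (ppm).
#' @slot nscale the 15N scaling divisor used in the CSP formula (default 5).
#' @export
setClass("CSPProfile",
  representation(label = "character", data = "data.frame",
                 cspMax = "numeric", threshold = "numeric",
                 nscale = "numeric"),
  validity = function(object) {
    d <- object@data
    need <- c("resno", "csp", "status", "colour")
    if (!all(need %in% names(d)))
      return(paste("data lacks columns:",
                   paste(setdiff(need, names(d)), collapse = ", ")))
    if (any(d$csp < 0, na.rm = TRUE)) return("negative CSP")
    if (any(d$colour < 0 | d$colour > 1, na.rm = TRUE))
      return("colour values outside [0,1]")
    TRUE
  })

#' RelaxationSeries: one residue's relaxation decay across a delay schedule
#'
#' Duplicate delays are legitimate (they check reproducibility) and are kept
#' as independent observations.
#'
#' @slot resno residue number.
#' @slot kind `"T1"` or `"T1rho"`.
#' @slot delays delay times, ms.
#' @slot intensities one peak intensity per delay (spectrum units).
#' @slot noise spectrum RMS noise estimate (same units).
#' @export
setClass("RelaxationSeries",
  representation(resno = "integer", kind = "character",
                 delays = "numeric", intensities = "numeric",
                 noise = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("T1", "T1rho")) return("kind must be T1 or T1rho")
    if (length(object@delays) != length(object@intensities))
      return("delays and intensities differ in length")
    if (length(unique(object@delays)) < 4L)
      return("fewer than 4 distinct delays")
    if (!all(is.finite(object@intensities))) return("non-finite intensities")
    TRUE
  })

#' FieldContext: spectrometer field and spin-lock parameters
#'
#' @slot h1MHz 1H resonance frequency, MHz.
#' @slot nuNHz 15N resonance frequency, Hz.
#' @slot b1kHz spin-lock field strength, kHz.
#' @slot carrierPpm spin-lock carrier offset, ppm.
#' @export
setClass("FieldContext",
  representation(h1MHz = "numeric", nuNHz = "numeric",
                 b1kHz = "numeric", carrierPpm = "numeric"),
  validity = function(object) {
    if (object@h1MHz <= 0 || object@nuNHz <= 0 || object@b1kHz <= 0)
      return("frequencies and field strength must be positive")
    TRUE
  })

#' ExchangeTable: per-residue solvent-exchange observables and classes
#'
#' Holds normalised CLEANEX-PM intensities, the 3/12/39 h real-time
#' intensities and (once classified) the exchange class for each residue.
#'
#' @slot data data.frame with columns `resno`, `cleanex`, `reference`,
#'   `i3`, `i12`, `i39` (intensities, `NA` when absent), `noise`, `class`
#'   (`NA` until classified; one of `"fast"`, `"slow-light"`,
#'   `"slow-medium"`, `"slow-dark"`, `"unobserved"`).
#' @export
setClass("ExchangeTable",
  representation(data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("resno", "cleanex", "reference", "i3", "i12", "i39",
              "noise", "class")
    if (!all(need %in% names(d)))
      return(paste("data lacks columns:",
                   paste(setdiff(need, names(d)), collapse = ", ")))
    if (anyDuplicated(d$resno)) return("duplicate residue numbers")
    kn <- c("fast", "slow-light", "slow-medium", "slow-dark", "unobserved")
    bad <- setdiff(unique(d$class[!is.na(d$class)]), kn)
    if (length(bad)) return(paste("unknown class:", paste(bad, collapse = ",")))
    TRUE
  })

#' SyntheticTruth: recorded ground truth of a synthetic scenario
#'
#' @slot scenario scenario label.
#' @slot params named list of planted parameters (hinge rotation, planted CSP
#'   magnitudes, decay constants, exchange rates, ... depending on scenario).
#' @slot seed the RNG seed used; regenerating with the same seed reproduces
#'   byte-identical outputs.
#' @export
setClass("SyntheticTruth",
  representation(scenario = "character", params = "list", seed = "integer"))

#' ComparisonReport: aggregated study results across samples
#'
#' @slot reference label of the reference sample.
#' @slot csp data.frame summarising each comparison's CSP profile.
#' @slot relaxation data.frame of per-sample HD/ART tau_c means.
#' @slot exchange data.frame of per-sample exchange class counts.
#' @slot rmsd data.frame of Table-2-style superposition rows.
#' @slot affinity data.frame of KD fold changes (empty when no KD table given).
#' @slot warnings character vector of collected per-stage warnings/flags.
#' @export
setClass("ComparisonReport",
  representation(reference = "character", csp = "data.frame",
                 relaxation = "data.frame", exchange = "data.frame",
                 rmsd = "data.frame", affinity = "data.frame",
                 warnings = "character"))
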