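#' CLEANEX-PM normalisation factor
#'
#' Samples differ in concentration and receiver settings, so CLEANEX-PM
#' intensities are made comparable between samples by the factor
#' `(sum of CLEANEX intensities / sum of reference-spectrum intensities)`
#' over a small set of unstructured, fast-exchanging reference residues. The
#' defaults (657, 660, 661) are N-terminal residues that exchange freely and
#' are unaffected by ligand binding or subdomain mutation.
#'
#' @param cleanex,reference data.frames with columns `resno`, `intensity`.
#' @param refResidues residue numbers used for the factor.
#' @return scalar normalisation factor.
#' @export
cleanexFactor <- function(cleanex, reference, refResidues = c(657, 660, 661)) {
  get <- function(tbl, what) {
    i <- match(refResidues, tbl$resno)
    if (anyNA(i))
      stop("reference residue(s) missing from ", what, " table: ",
           paste(refResidues[is.na(i)], collapse = ", "))
    v <- tbl$intensity[i]
    if (any(!is.finite(v) | v <= 0))
      stop("non-positive reference intensity in ", what, " table for residue(s): ",
           paste(refResidues[!is.finite(v) | v <= 0], collapse = ", "))
    v
  }
  sum(get(cleanex, "CLEANEX")) / sum(get(reference, "reference"))
}

#' Normalise a CLEANEX intensity table by a sample factor
#'
#' @param cleanex data.frame with columns `resno`, `intensity`.
#' @param factor positive normalisation factor from [cleanexFactor()].
#' @return the table with every intensity divided by `factor`.
#' @export
normaliseCleanex <- function(cleanex, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0)
    stop("normalisation factor must be a single positive number")
  cleanex$intensity <- cleanex$intensity / factor
  cleanex
}

#' Classify a slowly exchanging residue from its 3/12/39 h intensities
#'
#' The three slow classes partition the positive intensity triples:
#' \itemize{
#'   \item `slow-light`: `I(3h) - I(12h) > 0.5 * I(3h)` (most of the signal
#'     is gone by 12 h);
#'   \item `slow-medium`: not light, and `I(12h) - I(39h) > 0.25 * I(12h)`;
#'   \item `slow-dark`: neither (the signal persists to 39 h).
#' }
#' Equality at either boundary goes to the slower class: the defining
#' inequalities are strict on both sides, leaving the boundary open, and the
#' slower class is the conservative protection call.
#'
#' @param i3,i12,i39 intensities at 3, 12 and 39 h (all present, >= 0).
#' @return one of `"slow-light"`, `"slow-medium"`, `"slow-dark"`.
#' @export
classifySlow <- function(i3, i12, i39) {
  v <- c(i3, i12, i39)
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
    stop("all three intensities must be present and non-negative")
  if ((i3 - i12) > 0.5 * i3) return("slow-light")
  if ((i12 - i39) > 0.25 * i12) return("slow-medium")
  "slow-dark"
}

#' Classify one residue's solvent-exchange regime
#'
#' Rule precedence: a CLEANEX-PM signal above the detection threshold marks
#' the residue `fast` (it exchanges on the sub-second timescale); otherwise
#' a real-time 3 h signal above threshold routes to [classifySlow()] (later
#' time points below threshold are floored at the threshold noise level,
#' i.e. treated as 0); otherwise the residue is `unobserved` — either its
#' signal is missing for spectroscopic reasons or its rate falls in the
#' blind window between the two experiments.
#'
#' @param record one-row list/data.frame with fields `cleanex`, `i3`, `i12`,
#'   `i39` (intensities or `NA`) and `noise` (RMS spectrum noise).
#' @param threshold detection threshold as a multiple of `noise`
#'   (default 3).
#' @return the class string.
#' @export
classifyResidue <- function(record, threshold = 3) {
  .assertScalarPositive(threshold, "threshold")
  noise <- if (!is.null(record$noise) && is.finite(record$noise))
    record$noise else 0
  floorv <- threshold * noise
  seen <- function(x) !is.null(x) && length(x) == 1L && is.finite(x) &&
    x > floorv
  if (seen(record$cleanex)) return("fast")
  if (seen(record$i3)) {
    g <- function(x) if (seen(x)) x else 0
    return(classifySlow(record$i3, g(record$i12), g(record$i39)))
  }
  "unobserved"
}

#' Classify every residue of an ExchangeTable
#'
#' @param table an [ExchangeTable-class].
#' @param threshold detection threshold (multiple of per-residue noise).
#' @return the table with the `class` column filled.
#' @export
classifyTable <- function(table, threshold = 3) {
  stopifnot(is(table, "ExchangeTable"))
  d <- table@data
  d$class <- vapply(seq_len(nrow(d)), function(i)
    classifyResidue(as.list(d[i, ]), threshold), "")
  table@data <- d
  table
}

setMethod("show", "ExchangeTable", function(object) {
  d <- object@data
  cat("ExchangeTable: ", nrow(d), " residues", sep = "")
  if (any(!is.na(d$class))) {
    tab <- table(d$class)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
})

#' Predicted exchange class for a first-order rate
#'
#' Evaluates the ideal observables of a residue exchanging with rate `k`:
#' above the CLEANEX-detectable floor the residue is `fast` (the random-coil
#' rate at pH 7 / 25 C, ~10 /s, sits squarely in this regime); below it the
#' real-time intensities `I(t) = exp(-k t)` at the 3/12/39 h points are fed
#' to [classifySlow()], unless even the 3 h signal falls below the detection
#' floor, which yields `unobserved`.
#'
#' @param k exchange rate (> 0).
#' @param units `"s"` for per-second (default) or `"h"` for per-hour.
#' @param times real-time sampling points in hours (default 3, 12, 39).
#' @param cleanexFloor lower edge of CLEANEX detectability, per second
#'   (default 0.5 — the lower bound of the blind window; rates between this
#'   and the real-time-visible regime cannot be observed by either
#'   experiment, but any rate at or above it is in the fast regime).
#' @param detectionFloor minimum relative intensity counted as a signal in
#'   the real-time series (default 1e-3).
#' @return the class string.
#' @examples
#' simulateClassFromRate(0.2, units = "h")   # slow-light
#' simulateClassFromRate(10)                 # fast
#' @export
simulateClassFromRate <- function(k, units = c("s", "h"),
                                  times = c(3, 12, 39),
                                  cleanexFloor = 0.5,
                                  detectionFloor = 1e-3) {
  units <- match.arg(units)
  .assertScalarPositive(k, "k")
  kps <- if (units == "h") k / 3600 else k   # rate in /s
  if (kps >= cleanexFloor) return("fast")
  I <- exp(-kps * 3600 * times)
  if (I[1L] < detectionFloor) return("unobserved")
  classifySlow(I[1L], I[2L], I[3L])
}

#' Assemble an ExchangeTable from per-spectrum intensity tables
#'
#' @param cleanex,reference data.frames (`resno`, `intensity`) or `NULL`.
#' @param realtime named list of data.frames keyed `"3"`, `"12"`, `"39"`
#'   (hours), each (`resno`, `intensity`); missing spectra allowed.
#' @param noise RMS spectrum noise applied to every residue.
#' @param normalise divide CLEANEX intensities by the [cleanexFactor()]
#'   computed from `cleanex` and `reference` (default `TRUE` when both
#'   tables are present).
#' @param refResidues reference residues for the factor.
#' @return an [ExchangeTable-class] (unclassified).
#' @export
exchangeTable <- function(cleanex = NULL, reference = NULL, realtime = list(),
                          noise = 0,
                          normalise = !is.null(cleanex) && !is.null(reference),
                          refResidues = c(657, 660, 661)) {
  if (normalise) {
    f <- cleanexFactor(cleanex, reference, refResidues)
    cleanex <- normaliseCleanex(cleanex, f)
  }
  resno <- sort(unique(c(if (!is.null(cleanex)) cleanex$resno,
                         if (!is.null(reference)) reference$resno,
                         unlist(lapply(realtime, `[[`, "resno")))))
  pick <- function(tbl) if (is.null(tbl)) rep(NA_real_, length(resno))
    else tbl$intensity[match(resno, tbl$resno)]
  d <- data.frame(resno = resno,
                  cleanex = pick(cleanex), reference = pick(reference),
                  i3 = pick(realtime[["3"]]), i12 = pick(realtime[["12"]]),
                  i39 = pick(realtime[["39"]]), noise = noise,
                  class = NA_character_, stringsAsFactors = FALSE)
  new("ExchangeTable", data = d)
}

#' Write per-residue exchange classes as a viewer attribute file
#'
#' Encodes the classes with the conventional colours: fast = red, the three
#' slow classes = light/medium/dark blue, unobserved = white.
#'
#' @param table a classified [ExchangeTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportExchangeAttributes <- function(table, path) {
  cols <- c(fast = "red", `slow-light` = "lightblue",
            `slow-medium` = "mediumblue", `slow-dark` = "darkblue",
            unobserved = "white")
  d <- table@data[order(table@data$resno), ]
  lines <- sprintf("%d\t%s\t%s", d$resno,
                   ifelse(is.na(d$class), "unclassified", d$class),
                   ifelse(is.na(d$class), "", cols[d$class]))
  writeLines(c("resno\tclass\tcolour", lines), path)
  invisible(path)
}
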