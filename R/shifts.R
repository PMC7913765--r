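#' Read a per-residue amide chemical-shift table
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`tsv`}{tab- or whitespace-separated columns with a header line;
#'     recognised column names (case-insensitive): `resno`/`residue`/`res`,
#'     `code`/`aa`, `dH`/`h`/`1h`, `dN`/`n`/`15n`, optional `status`.}
#'   \item{`sparky`}{Sparky resonance-list style: one line per amide,
#'     `G888N-H  110.552  8.231` (assignment, 15N ppm, 1H ppm).}
#'   \item{`nmrstar`}{a minimal NMR-STAR 3 chemical-shift loop reader:
#'     scans the `_Atom_chem_shift` loop for `Comp_index_ID`, `Comp_ID`,
#'     `Atom_ID` and `Val` and combines the H/N rows per residue. Sufficient
#'     for BMRB backbone-amide depositions; it is not a general STAR parser.}
#' }
#' Prolines are auto-flagged from the residue code (their amide has no NH);
#' assigned shifts falling outside the amide-plausible windows (1H 5-13 ppm,
#' 15N 95-140 ppm) trigger a warning, not an error.
#'
#' @param path input file.
#' @param dialect `"tsv"`, `"sparky"` or `"nmrstar"`.
#' @param label sample label (defaults to the file base name).
#' @return a [ShiftTable-class].
#' @export
readShiftTable <- function(path, dialect = c("tsv", "sparky", "nmrstar"),
                           label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  d <- switch(dialect,
              tsv = .readShiftTsv(path),
              sparky = .readShiftSparky(path),
              nmrstar = .readShiftStar(path))
  shiftTable(label, d$resno, d$code, d$dH, d$dN, d$status)
}

#' Construct a ShiftTable from vectors
#'
#' @param label sample label.
#' @param resno residue numbers (unique).
#' @param code one-letter residue codes.
#' @param dH,dN amide 1H and 15N shifts, ppm (`NA` where unassigned).
#' @param status optional status vector; defaults to `"assigned"` where both
#'   shifts are present and `"unassigned"` otherwise. Prolines are always
#'   forced to status `"proline"`.
#' @return a [ShiftTable-class].
#' @export
shiftTable <- function(label, resno, code, dH, dN, status = NULL) {
  resno <- as.integer(resno)
  if (anyDuplicated(resno))
    stop("duplicate residue rows: ",
         paste(unique(resno[duplicated(resno)]), collapse = ", "))
  if (is.null(status))
    status <- ifelse(is.finite(dH) & is.finite(dN), "assigned", "unassigned")
  status[toupper(code) %in% c("P", "PRO")] <- "proline"
  ok <- status == "assigned"
  if (any(ok & (dH < 5 | dH > 13), na.rm = TRUE))
    warning("1H shifts outside the 5-13 ppm amide window")
  if (any(ok & (dN < 95 | dN > 140), na.rm = TRUE))
    warning("15N shifts outside the 95-140 ppm amide window")
  dH[!ok] <- NA_real_; dN[!ok] <- NA_real_
  o <- order(resno)
  new("ShiftTable", label = label,
      data = data.frame(resno = resno, code = as.character(code),
                        dH = as.numeric(dH), dN = as.numeric(dN),
                        status = status,
                        stringsAsFactors = FALSE)[o, , drop = FALSE])
}

#' @describeIn ShiftTable-class per-residue shift data accessor.
#' @param x a `ShiftTable`.
#' @export
shifts <- function(x) x@data

#' @describeIn ShiftTable-class sample label accessor.
#' @export
sampleLabel <- function(x) x@label

setMethod("show", "ShiftTable", function(object) {
  d <- object@data
  cat("ShiftTable '", object@label, "': ", nrow(d), " residues (",
      sum(d$status == "assigned"), " assigned, ",
      sum(d$status == "proline"), " proline)\n", sep = "")
})

.readShiftTsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  nm <- tolower(names(d))
  pick <- function(cands, what, required = TRUE) {
    i <- which(nm %in% cands)[1L]
    if (is.na(i)) {
      if (required) stop("missing ", what, " column (expected one of: ",
                         paste(cands, collapse = ", "), ")")
      return(NULL)
    }
    d[[i]]
  }
  resno <- pick(c("resno", "residue", "res"), "residue-number")
  code <- pick(c("code", "aa", "restype"), "residue-code", required = FALSE)
  if (is.null(code)) code <- rep("X", length(resno))
  dH <- pick(c("dh", "h", "1h", "d1h"), "1H shift")
  dN <- pick(c("dn", "n", "15n", "d15n"), "15N shift")
  status <- pick("status", "status", required = FALSE)
  if (anyDuplicated(resno))
    stop("duplicate residue rows in ", path)
  list(resno = resno, code = code, dH = as.numeric(dH), dN = as.numeric(dN),
       status = status)
}

.readShiftSparky <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^(Assignment|#)", lines)]
  m <- regmatches(lines,
                  regexec("^([A-Z])(\\d+)N-H[N]?\\s+([-0-9.]+)\\s+([-0-9.]+)",
                          lines))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("unparseable Sparky line: '", lines[bad][1L], "'")
  code <- vapply(m, `[`, "", 2L)
  resno <- as.integer(vapply(m, `[`, "", 3L))
  if (anyDuplicated(resno)) stop("duplicate residue rows in ", path)
  # Sparky lists w1 (15N) before w2 (1H)
  list(resno = resno, code = code,
       dH = as.numeric(vapply(m, `[`, "", 5L)),
       dN = as.numeric(vapply(m, `[`, "", 4L)),
       status = NULL)
}

# one-letter codes for the shift tables
.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.readShiftStar <- function(path) {
  lines <- readLines(path)
  # locate the atom chemical-shift loop and its tag block
  tagIdx <- grep("^\\s*_Atom_chem_shift\\.", lines)
  if (!length(tagIdx)) stop("no _Atom_chem_shift loop found in ", path)
  tags <- sub("^\\s*_Atom_chem_shift\\.(\\S+).*$", "\\1", lines[tagIdx])
  need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
  col <- match(need, tags)
  if (anyNA(col))
    stop("chemical-shift loop lacks tags: ",
         paste(need[is.na(col)], collapse = ", "))
  dataStart <- max(tagIdx) + 1L
  rows <- list()
  for (ln in lines[dataStart:length(lines)]) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (t == "stop_" || startsWith(t, "loop_") || startsWith(t, "_")) break
    f <- strsplit(t, "\\s+")[[1L]]
    if (length(f) < max(col)) next
    rows[[length(rows) + 1L]] <- f[col]
  }
  if (!length(rows)) stop("empty chemical-shift loop in ", path)
  m <- do.call(rbind, rows)
  df <- data.frame(resno = as.integer(m[, 1L]), comp = m[, 2L],
                   atom = m[, 3L], val = as.numeric(m[, 4L]),
                   stringsAsFactors = FALSE)
  df <- df[df$atom %in% c("H", "HN", "N"), , drop = FALSE]
  byres <- split(df, df$resno)
  resno <- as.integer(names(byres))
  dH <- vapply(byres, function(s) {
    v <- s$val[s$atom %in% c("H", "HN")]
    if (length(v)) v[1L] else NA_real_
  }, numeric(1))
  dN <- vapply(byres, function(s) {
    v <- s$val[s$atom == "N"]
    if (length(v)) v[1L] else NA_real_
  }, numeric(1))
  comp <- vapply(byres, function(s) s$comp[1L], "")
  code <- unname(ifelse(toupper(comp) %in% names(.aa321),
                        .aa321[toupper(comp)], "X"))
  o <- order(resno)
  list(resno = resno[o], code = code[o], dH = unname(dH)[o],
       dN = unname(dN)[o], status = NULL)
}
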