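#' Read a protein structure from a PDB or mmCIF file
#'
#' Wraps bio3d's parsers and returns a [StructureModel-class] with occupancy
#' and alternate-location tags preserved and coordinates in Angstrom. Waters
#' and hydrogens are retained in the model; selections exclude them by
#' default (see [resolveAtoms()]).
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (default: guess from the file
#'   extension, falling back to PDB).
#' @param id optional model label; defaults to the file base name.
#' @return a [StructureModel-class].
#' @examples
#' pair <- makeTwoDomainPair(20, 20, hingeAngle = 0, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(pair$reference, f)
#' m <- readStructure(f)
#' nrow(atoms(m))
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path)
    else bio3d::read.pdb(path, rm.alt = FALSE),  # altlocs resolved later
    error = function(e) stop("unreadable ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model: no atoms in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resno = as.integer(a$resno),
    resname = as.character(a$resid),
    name = as.character(a$elety),
    element = if ("elesy" %in% names(a)) as.character(a$elesy) else
      substr(gsub("[^A-Za-z].*$", "", a$elety), 1L, 1L),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
    stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.(pdb|cif|mmcif|ent)$", "",
                             basename(path), ignore.case = TRUE)
  new("StructureModel", id = id, atoms = atoms)
}

#' Write a StructureModel to a minimal PDB file
#'
#' Emits standard fixed-width ATOM records (author numbering, occupancy,
#' altloc) — enough for round-tripping synthetic models and exchanging
#' coordinates with other tools.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name),
    ifelse(a$alt == "", " ", a$alt),
    a$resname, ifelse(a$chain == "", " ", a$chain), a$resno,
    a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @describeIn StructureModel-class atom table accessor.
#' @param model a `StructureModel`.
#' @export
atoms <- function(model) model@atoms

#' @describeIn StructureModel-class model label accessor.
#' @export
modelId <- function(model) model@id

#' @describeIn StructureModel-class chain identifiers present in the model.
#' @export
chains <- function(model) unique(atoms(model)$chain)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel '", object@id, "': ",
      length(unique(a$chain)), " chain(s) [",
      paste(unique(a$chain), collapse = ","), "], ",
      length(unique(paste(a$chain, a$resno))), " residues, ",
      nrow(a), " atoms\n", sep = "")
})

# Resolve alternate locations within one chain's atom table: for each
# (resno, atom name), keep altloc '' or 'A'; if neither is present keep the
# highest-occupancy location, breaking ties by altloc label order.
resolveAltloc <- function(a) {
  key <- paste(a$resno, a$name, sep = "|")
  if (!anyDuplicated(key)) return(a)
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- a[idx, , drop = FALSE]
    pref <- idx[sub$alt %in% c("", "A")]
    if (length(pref)) return(pref[order(a$alt[pref])][1L])
    idx[order(-sub$occ, sub$alt)][1L]
  }), use.names = FALSE)
  a[sort(keep), , drop = FALSE]
}
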