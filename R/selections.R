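#' Construct an atom selection
#'
#' @param name selection label.
#' @param ranges two-column matrix or data.frame of inclusive residue-number
#'   ranges (start, end), or a list of length-2 vectors.
#' @param atoms character vector of atom names applied to every range
#'   (default backbone N, CA, C).
#' @param chain chain id applied to every range, or `NA` to take the chain
#'   supplied at resolution time.
#' @return an [AtomSelection-class].
#' @examples
#' atomSelection("HD", list(c(666, 721), c(730, 743), c(750, 779)))
#' @export
atomSelection <- function(name, ranges, atoms = c("N", "CA", "C"),
                          chain = NA_character_) {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2L) stop("ranges must have two columns (start, end)")
  items <- data.frame(chain = chain,
                      start = as.integer(ranges[, 1L]),
                      end = as.integer(ranges[, 2L]),
                      atoms = paste(atoms, collapse = ","),
                      stringsAsFactors = FALSE)
  new("AtomSelection", name = name, items = items)
}

# subdomain residue ranges used throughout: CAT = HD + ART backbone
.builtinRanges <- list(
  HD  = list(c(666, 721), c(730, 743), c(750, 779)),
  ART = list(c(790, 936), c(939, 1009)),
  CAT = list(c(666, 721), c(730, 743), c(750, 779),
             c(790, 936), c(939, 1009)))

#' Built-in CAT / HD / ART backbone selections
#'
#' The subdomain definitions used for all superposition statistics:
#' CAT = 666-721, 730-743, 750-779, 790-936, 939-1009;
#' HD = 666-721, 730-743, 750-779; ART = 790-936, 939-1009
#' (backbone N, CA, C in every case).
#'
#' @param name `"CAT"`, `"HD"` or `"ART"`.
#' @return an [AtomSelection-class].
#' @examples
#' builtinSelection("ART")
#' @export
builtinSelection <- function(name = c("CAT", "HD", "ART")) {
  name <- match.arg(name)
  atomSelection(name, .builtinRanges[[name]])
}

#' Parse a selection from the "chain:start-end:atoms" grammar
#'
#' Items are separated by `;` or `+`. The chain field may be empty
#' (`":666-721:N,CA,C"`) to defer the chain to resolution time; the atoms
#' field may be omitted to mean backbone `N,CA,C`.
#'
#' @param text selection string, e.g. `"A:666-721:N,CA,C; A:730-743:N,CA,C"`.
#' @param name selection label (defaults to the text itself).
#' @return an [AtomSelection-class].
#' @export
parseSelection <- function(text, name = text) {
  parts <- trimws(strsplit(text, "[;+]")[[1L]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty selection string")
  rows <- lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed selection item '", p,
                             "': expected chain:start-end[:atoms]")
    rng <- as.integer(strsplit(f[2L], "-", fixed = TRUE)[[1L]])
    if (length(rng) == 1L) rng <- c(rng, rng)
    if (length(rng) != 2L || any(is.na(rng)))
      stop("malformed residue range in '", p, "'")
    atoms <- if (length(f) >= 3L && nzchar(f[3L]))
      trimws(strsplit(f[3L], ",", fixed = TRUE)[[1L]]) else c("N", "CA", "C")
    data.frame(chain = if (nzchar(f[1L])) f[1L] else NA_character_,
               start = rng[1L], end = rng[2L],
               atoms = paste(atoms, collapse = ","),
               stringsAsFactors = FALSE)
  })
  new("AtomSelection", name = name, items = do.call(rbind, rows))
}

setMethod("show", "AtomSelection", function(object) {
  it <- object@items
  cat("AtomSelection '", object@name, "': ",
      paste(sprintf("%s:%d-%d:%s",
                    ifelse(is.na(it$chain), "*", it$chain),
                    it$start, it$end, it$atoms), collapse = "; "),
      "\n", sep = "")
})

#' Resolve an atom selection against a structure
#'
#' Emits one row per requested atom in selection order. Atoms missing from
#' the model are flagged absent in the mask, never silently dropped, so two
#' structures can later be paired on the intersection of their masks.
#' Alternate locations are resolved first (keep `''`/`'A'`, else highest
#' occupancy, ties by label order); hydrogens and waters are excluded.
#'
#' @param model a [StructureModel-class].
#' @param selection an [AtomSelection-class].
#' @param chain chain id used for items whose chain is `NA` (default `"A"`).
#' @return data.frame with columns `chain`, `resno`, `name`, `x`, `y`, `z`,
#'   `present` (logical mask).
#' @export
resolveAtoms <- function(model, selection, chain = "A") {
  stopifnot(is(model, "StructureModel"), is(selection, "AtomSelection"))
  a <- atoms(model)
  a <- a[!(a$resname %in% c("HOH", "WAT", "DOD")) &
           !(a$element %in% c("H", "D")), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(selection@items))) {
    it <- selection@items[i, ]
    ch <- if (is.na(it$chain)) chain else it$chain
    sub <- a[a$chain == ch & a$resno >= it$start & a$resno <= it$end, ,
             drop = FALSE]
    if (nrow(sub)) sub <- resolveAltloc(sub)
    wanted <- trimws(strsplit(it$atoms, ",", fixed = TRUE)[[1L]])
    grid <- expand.grid(name = wanted, resno = it$start:it$end,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # selection order: by residue, then atom-name order as given
    grid <- grid[order(grid$resno, match(grid$name, wanted)), ]
    idx <- match(paste(grid$resno, grid$name),
                 paste(sub$resno, sub$name))
    out[[i]] <- data.frame(
      chain = ch, resno = grid$resno, name = grid$name,
      x = sub$x[idx], y = sub$y[idx], z = sub$z[idx],
      present = !is.na(idx), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!any(res$present))
    stop("selection '", selection@name, "' resolves to zero atoms on chain ",
         chain, " of model '", modelId(model), "'")
  res
}
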