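#' Molecule: a parsed SMILES record
#'
#' An S4 container for one molecule parsed from SMILES. Atoms carry element
#' symbol, aromaticity flag (from lowercase input or Hueckel perception),
#' formal charge, isotope, explicit bracket hydrogen count (\code{-1} when the
#' atom was unbracketed and hydrogens are implicit), the resolved hydrogen
#' count \code{nH}, and whether a tetrahedral stereo marker (\code{@}) was
#' present in the input (the marker itself is discarded). Bonds carry order
#' (1, 2, 3) and an aromatic flag.
#'
#' @slot smiles Input SMILES string as supplied.
#' @slot id Record identifier (defaults to the input line number).
#' @slot atoms data.frame of per-atom properties.
#' @slot bonds data.frame of bonds (columns \code{from}, \code{to},
#'   \code{order}, \code{aromatic}).
#'
#' @seealso [parseMolecule()], [extractShingles()], [computeTriplet()]
#' @export
setClass("Molecule", representation(
  smiles = "character",
  id = "character",
  atoms = "data.frame",
  bonds = "data.frame"
))

#' Parse a SMILES string into a Molecule
#'
#' Parses SMILES, perceives aromaticity of Kekule-form rings under a
#' simplified Hueckel model, assigns implicit hydrogens, and discards all
#' stereochemistry. Aromatic lowercase input is taken as authoritative.
#' Disconnected (dot-separated) input is supported; all downstream operations
#' treat components separately and pool results.
#'
#' @param smiles A single SMILES string.
#' @param id Record identifier; defaults to \code{"1"}.
#' @param fragment Parse as a fragment string (e.g. a shingle): lowercase
#'   aromatic flags are taken verbatim, unmarked bonds between aromatic atoms
#'   are aromatic even outside complete rings, and no ring perception runs.
#'   Molecule-level parsing (the default) instead perceives aromaticity from
#'   rings and demotes non-ring aromatic-default bonds (the biphenyl linker)
#'   to single bonds.
#' @return A [Molecule-class] object.
#' @examples
#' mol <- parseMolecule("CCO", "ethanol")
#' hac(mol)
#' @export
parseMolecule <- function(smiles, id = "1", fragment = FALSE) {
  g <- .parseSmilesGraph(smiles)
  if (fragment) {
    g$barom <- g$bexplicit == ":" |
      (g$bexplicit == "" & g$arom[g$bfrom] & g$arom[g$bto])
    if (length(g$barom) == 0L) g$barom <- logical(0)
  } else {
    rings <- .simpleRings(length(g$sym), g$bfrom, g$bto)
    g <- .perceiveAromaticity(g, rings)
  }
  g <- .foldExplicitHydrogens(g)
  g <- .resolveHydrogens(g)
  atoms <- data.frame(
    symbol = g$sym, aromatic = g$arom, charge = g$charge,
    isotope = g$isotope, hExplicit = g$hexp, nH = g$nH,
    stereoMarked = g$stereo, stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    from = g$bfrom, to = g$bto, order = g$border, aromatic = g$barom,
    stringsAsFactors = FALSE
  )
  methods::new("Molecule", smiles = smiles, id = as.character(id),
               atoms = atoms, bonds = bonds)
}

## Fold explicit [H] atoms into their heavy neighbour (internal).
.foldExplicitHydrogens <- function(g) {
  hs <- which(g$sym == "H")
  if (length(hs) == 0L) return(g)
  if (any(g$charge[hs] != 0L) || any(g$isotope[hs] != 0L))
    return(g)  # charged/isotopic hydrogens kept as graph atoms (e.g. [2H])
  drop <- logical(length(g$sym))
  for (h in hs) {
    bs <- which(g$bfrom == h | g$bto == h)
    if (length(bs) != 1L || g$border[bs] != 1L)
      .parse_error("explicit H atom with non-single bonding", "")
    nbr <- setdiff(c(g$bfrom[bs], g$bto[bs]), h)
    if (g$sym[nbr] == "H") next  # H2: keep as-is
    if (g$hexp[nbr] >= 0L) g$hexp[nbr] <- g$hexp[nbr] + 1L
    drop[h] <- TRUE
  }
  if (!any(drop)) return(g)
  keep <- which(!drop)
  remap <- integer(length(g$sym)); remap[keep] <- seq_along(keep)
  bkeep <- !(g$bfrom %in% which(drop) | g$bto %in% which(drop))
  list(sym = g$sym[keep], arom = g$arom[keep], charge = g$charge[keep],
       isotope = g$isotope[keep], hexp = g$hexp[keep], stereo = g$stereo[keep],
       bfrom = remap[g$bfrom[bkeep]], bto = remap[g$bto[bkeep]],
       border = g$border[bkeep], bexplicit = g$bexplicit[bkeep],
       barom = g$barom[bkeep])
}

#' @describeIn Molecule-class Number of heavy (non-hydrogen) atoms.
#' @param object,x A \code{Molecule}.
#' @export
setGeneric("hac", function(x) standardGeneric("hac"))

#' @rdname Molecule-class
#' @export
setMethod("hac", "Molecule", function(x) nrow(x@atoms))

#' @describeIn Molecule-class Number of heteroatoms (heavy atoms that are not
#'   carbon).
#' @export
setGeneric("heteroAtomCount", function(x) standardGeneric("heteroAtomCount"))

#' @rdname Molecule-class
#' @export
setMethod("heteroAtomCount", "Molecule",
          function(x) sum(x@atoms$symbol != "C"))

#' @describeIn Molecule-class Record identifier.
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))

#' @rdname Molecule-class
#' @export
setMethod("molId", "Molecule", function(x) x@id)

#' @describeIn Molecule-class Input SMILES string.
#' @export
setGeneric("molSmiles", function(x) standardGeneric("molSmiles"))

#' @rdname Molecule-class
#' @export
setMethod("molSmiles", "Molecule", function(x) x@smiles)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s' (%s)\n", object@id, object@smiles))
  cat(sprintf("  %d heavy atoms, %d bonds, %d aromatic atoms, %d heteroatoms\n",
              hac(object), nrow(object@bonds), sum(object@atoms$aromatic),
              heteroAtomCount(object)))
  invisible(object)
})

#' Read a SMILES file
#'
#' One record per line: a SMILES string optionally followed by whitespace and
#' an identifier. Lines beginning with \code{#} and blank lines are ignored.
#' Missing identifiers default to the line number.
#'
#' @param path Path to the SMILES file.
#' @return data.frame with columns \code{smiles}, \code{id}, \code{line}
#'   (original line number) and \code{text} (the verbatim line).
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L)
    return(data.frame(smiles = character(0), id = character(0),
                      line = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  data.frame(
    smiles = vapply(toks, `[[`, character(1), 1L),
    id = vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2L) toks[[i]][[2L]] else as.character(keep[i])
    }, character(1)),
    line = keep,
    text = lines[keep],
    stringsAsFactors = FALSE
  )
}

## Marshal a Molecule into the argument list the C++ kernels expect (internal).
.molArgs <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  list(
    sym = a$symbol,
    elem = match(a$symbol, .ELEMENTS),
    arom = as.integer(a$aromatic),
    charge = as.integer(a$charge),
    isotope = as.integer(a$isotope),
    hexp = as.integer(a$hExplicit),
    bondA = as.integer(b$from),
    bondB = as.integer(b$to),
    border = as.integer(b$order),
    barom = as.integer(b$aromatic)
  )
}
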