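#' Canonicalization tag of the shingle engine
#'
#' Shingle strings are only comparable when produced under the same parsing,
#' aromaticity and canonical-writing conventions. The tag identifies those
#' conventions; reference tables record it and scoring refuses to mix tags.
#'
#' @return A single character string.
#' @export
canonicalizationTag <- function() {
  "clscore/0.1;parser=builtin;aromaticity=hueckel-r7;stereo=stripped;hydrogens=implicit;charges=as-parsed"
}

#' Extract molecular shingles
#'
#' A shingle of radius r rooted at atom a is the connected fragment induced by
#' all bonds within r bonds of a, written as a canonical SMILES string that
#' starts at a, with aromatic atoms lowercase and stereochemistry discarded.
#' For every atom and every radius in \code{minRadius:maxRadius} at which the
#' molecule extends that far (at least one atom at topological distance
#' exactly r), one shingle is produced; the result contains each distinct
#' string once. Environments that do not reach the requested radius are not
#' emitted separately: they coincide with the full-radius shingle at their
#' true radius.
#'
#' @param mol A [Molecule-class].
#' @param minRadius,maxRadius Bond radii to enumerate (defaults 1 and 3).
#' @return data.frame with columns \code{text} (canonical fragment string) and
#'   \code{radius} (smallest radius at which the string occurred).
#' @examples
#' extractShingles(parseMolecule("CCC"))
#' @export
extractShingles <- function(mol, minRadius = 1L, maxRadius = 3L) {
  stopifnot(methods::is(mol, "Molecule"))
  if (!(minRadius >= 1L && minRadius <= maxRadius))
    stop("require 1 <= minRadius <= maxRadius")
  res <- do.call(cpp_extract_shingles,
                 c(.molArgs(mol), list(minRadius = as.integer(minRadius),
                                       maxRadius = as.integer(maxRadius))))
  data.frame(text = res$text, radius = res$radius, stringsAsFactors = FALSE)
}

#' Canonical rooted fragment string
#'
#' Renders the fragment of \code{mol} induced by \code{atomIds} (all bonds of
#' the molecule with both endpoints in the set) as a canonical SMILES string
#' whose first atom is \code{root}. Used by the shingle engine for every
#' (atom, radius) ball; exposed for testing and for custom fragment schemes.
#'
#' @param mol A [Molecule-class].
#' @param atomIds Integer atom indices (1-based) of the fragment; must be
#'   connected from the root.
#' @param root Atom index at which the string starts.
#' @param bondIds Optional integer bond indices (rows of \code{mol@bonds})
#'   making up the fragment. Default NULL uses every molecule bond with both
#'   endpoints in \code{atomIds}; pass the exact set when the fragment is a
#'   ball (a ball's bond set can be smaller than the induced one: an odd
#'   ring's closing bond joins only at a larger radius).
#' @return A single character string.
#' @export
canonicalFragment <- function(mol, atomIds, root, bondIds = NULL) {
  stopifnot(methods::is(mol, "Molecule"))
  do.call(cpp_canonical_fragment,
          c(.molArgs(mol), list(atomIds = as.integer(atomIds),
                                rootId = as.integer(root),
                                bondIds = as.integer(bondIds %||% integer(0)))))
}

#' Canonical SMILES of a whole molecule
#'
#' Canonical form under the engine's conventions (aromatic lowercase, no
#' stereochemistry): per connected component, the lexicographically smallest
#' rooted canonical string over all root atoms; components joined by '.' in
#' sorted order. Used for corpus deduplication and fixture bookkeeping.
#'
#' @param mol A [Molecule-class].
#' @return A single character string.
#' @export
canonicalSmiles <- function(mol) {
  comps <- .components(mol)
  parts <- vapply(comps, function(atoms) {
    strs <- vapply(atoms, function(a) canonicalFragment(mol, atoms, a),
                   character(1))
    min(strs)
  }, character(1))
  paste(sort(parts, method = "radix"), collapse = ".")
}

## Connected components as lists of atom index vectors (internal).
.components <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol@bonds))) {
    u <- mol@bonds$from[b]; v <- mol@bonds$to[b]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (comp[v] == 0L) { comp[v] <- k; queue <- c(queue, v) }
    }
  }
  split(seq_len(n), comp)
}

#' Symmetry classes of atoms
#'
#' Equitable-partition ranks from unrooted invariant refinement. Atoms in
#' different classes are guaranteed non-equivalent; used by the stereocenter
#' perception to decide whether a tetrahedral atom's substituents differ.
#'
#' @param mol A [Molecule-class].
#' @return Integer vector of class labels, one per atom.
#' @export
symmetryClasses <- function(mol) {
  stopifnot(methods::is(mol, "Molecule"))
  do.call(cpp_symmetry_classes, .molArgs(mol))
}

#' Re-render a molecule as a random SMILES string
#'
#' Writes a valid SMILES for the molecule starting from a random atom with
#' random branch ordering. Repeated calls enumerate alternative input
#' renderings of the same structure; shingle sets and CLscores are invariant
#' across them. Uses the current RNG state.
#'
#' @param mol A [Molecule-class].
#' @return A single character string.
#' @export
renderRandomSmiles <- function(mol) {
  comps <- .components(mol)
  parts <- vapply(comps, function(atoms) .writeComponent(mol, atoms),
                  character(1))
  paste(.shuffle(parts), collapse = ".")
}

## sample() that never falls into the length-1 integer trap (internal)
.shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

## Random-order SMILES writer for one connected component (internal).
.writeComponent <- function(mol, atoms) {
  a <- mol@atoms; b <- mol@bonds
  keepb <- which(b$from %in% atoms & b$to %in% atoms)
  adj <- lapply(seq_len(nrow(a)), function(i) integer(0))
  for (bi in keepb) {
    adj[[b$from[bi]]] <- c(adj[[b$from[bi]]], bi)
    adj[[b$to[bi]]] <- c(adj[[b$to[bi]]], bi)
  }
  token <- function(i) {
    sym <- a$symbol[i]
    s <- if (a$aromatic[i]) tolower(sym) else sym
    if (a$charge[i] == 0L && a$isotope[i] == 0L && a$hExplicit[i] < 0L &&
        sym %in% .ORGANIC) return(s)
    q <- a$charge[i]
    paste0("[",
           if (a$isotope[i] > 0L) a$isotope[i] else "",
           s,
           if (a$hExplicit[i] > 0L)
             paste0("H", if (a$hExplicit[i] > 1L) a$hExplicit[i] else ""),
           if (q > 0L) paste0("+", if (q > 1L) q else "")
           else if (q < 0L) paste0("-", if (q < -1L) -q else ""),
           "]")
  }
  bondch <- function(bi) {
    u <- b$from[bi]; v <- b$to[bi]
    if (b$aromatic[bi]) return(if (a$aromatic[u] && a$aromatic[v]) "" else ":")
    switch(b$order[bi], `1` = if (a$aromatic[u] && a$aromatic[v]) "-" else "",
           `2` = "=", `3` = "#")[[1]]
  }
  visited <- logical(nrow(a))
  bused <- logical(nrow(b))
  closures <- vector("list", nrow(a))
  children <- vector("list", nrow(a))
  digit <- 0L
  dfs <- function(u) {
    visited[u] <<- TRUE
    for (bi in .shuffle(adj[[u]])) {
      if (bused[bi]) next
      bused[bi] <<- TRUE
      v <- if (b$from[bi] == u) b$to[bi] else b$from[bi]
      if (visited[v]) {
        digit <<- digit + 1L
        ds <- if (digit < 10L) as.character(digit) else paste0("%", digit)
        closures[[v]] <<- c(closures[[v]], paste0(bondch(bi), ds))
        closures[[u]] <<- c(closures[[u]], ds)
      } else {
        children[[u]] <<- c(children[[u]], bi)
        dfs(v)
      }
    }
  }
  emit <- function(u) {
    s <- paste0(token(u), paste(closures[[u]], collapse = ""))
    ch <- children[[u]]
    for (k in seq_along(ch)) {
      bi <- ch[k]
      v <- if (b$from[bi] == u) b$to[bi] else b$from[bi]
      sub <- paste0(bondch(bi), emit(v))
      s <- if (k < length(ch)) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  root <- if (length(atoms) == 1L) atoms else sample(atoms, 1L)
  dfs(root)
  emit(root)
}
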