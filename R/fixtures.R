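## Synthetic corpora with known shingle statistics.
##
## The reference-corpus generator replicates scaffolds at chosen
## multiplicities, so every shingle unique to a scaffold ends up with a table
## count equal to that scaffold's multiplicity, and shared shingles with the
## sum over sharing scaffolds. The query generator draws from homologous
## families (alkanes, alcohols/ethers, amines, substituted aromatics) whose
## shingle overlap with typical reference scaffolds is controllable by
## construction. All randomness flows from explicit seeds; the caller's RNG
## state is untouched.

#' Generate a synthetic reference corpus
#'
#' Emits each scaffold exactly \code{multiplicity} times and shuffles the
#' lines under \code{shuffleSeed}. Downstream, a table built from this corpus
#' has exactly predictable counts: multiplicity for scaffold-specific
#' shingles, the sum of multiplicities for shared ones.
#'
#' @param scaffolds data.frame with columns \code{smiles} and
#'   \code{multiplicity} (integer >= 1).
#' @param shuffleSeed Integer seed for the line shuffle.
#' @return Character vector of SMILES lines.
#' @examples
#' lines <- generateReferenceCorpus(
#'   data.frame(smiles = "CCO", multiplicity = 150), shuffleSeed = 1)
#' length(buildReferenceTable(lines)@entries)  # 5 ethanol shingles
#' @export
generateReferenceCorpus <- function(scaffolds, shuffleSeed = 1L) {
  stopifnot(is.data.frame(scaffolds),
            all(c("smiles", "multiplicity") %in% names(scaffolds)))
  if (any(scaffolds$multiplicity < 1L))
    stop("scaffold multiplicities must be >= 1")
  for (s in scaffolds$smiles) parseMolecule(s)  # spec error before emission
  lines <- rep(scaffolds$smiles, times = scaffolds$multiplicity)
  .withSeed(shuffleSeed, .shuffle(lines))
}

## Random connected tree skeleton on k atoms with given symbols and a degree
## cap per element (internal; RNG assumed seeded).
.randomTreeSmiles <- function(symbols, maxDeg) {
  k <- length(symbols)
  deg <- integer(k)
  parent <- integer(k)
  for (i in seq_len(k)[-1L]) {
    open <- which(deg[seq_len(i - 1L)] < maxDeg[seq_len(i - 1L)])
    p <- if (length(open) == 1L) open else sample(open, 1L)
    parent[i] <- p
    deg[p] <- deg[p] + 1L
    deg[i] <- deg[i] + 1L
  }
  children <- if (k > 1L) split(seq_len(k)[-1L], parent[-1L]) else list()
  emit <- function(u) {
    ch <- children[[as.character(u)]]
    s <- symbols[u]
    for (j in seq_along(ch)) {
      sub <- emit(ch[j])
      s <- if (j < length(ch)) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  emit(1L)
}

.AROMATIC_CORES <- list(
  list(atoms = c("c", "c", "c", "c", "c", "c")),              # benzene
  list(atoms = c("c", "c", "n", "c", "c", "c")),              # pyridine
  list(atoms = c("c", "c", "s", "c", "c")),                   # thiophene
  list(atoms = c("c", "c", "o", "c", "c")),                   # furan
  list(atoms = c("c", "c", "[nH]", "c", "c"))                 # pyrrole
)

.AROMATIC_SUBS <- c("C", "CC", "C(C)C", "O", "N", "OC", "F", "Cl")

## Substituted aromatic ring SMILES (internal; RNG assumed seeded).
.randomAromaticSmiles <- function(hacTarget) {
  core <- .AROMATIC_CORES[[sample.int(length(.AROMATIC_CORES), 1L)]]$atoms
  npos <- length(core)
  budget <- hacTarget - npos
  subs <- character(npos)
  ## heavy-atom cost of a substituent = number of capital letters
  ## ("Cl" is C + lowercase l, i.e. one heavy atom)
  cost <- vapply(.AROMATIC_SUBS, function(s)
    sum(strsplit(s, "")[[1]] %in% LETTERS), integer(1))
  for (p in sample.int(npos)) {
    if (budget <= 0L) break
    if (core[p] %in% c("o", "s", "[nH]")) next  # divalent/NH positions stay bare
    cand <- .AROMATIC_SUBS[cost <= budget]
    if (length(cand) == 0L) break
    if (stats::runif(1) < 0.4) next
    s <- cand[sample.int(length(cand), 1L)]
    subs[p] <- paste0("(", s, ")")
    budget <- budget - sum(strsplit(s, "")[[1]] %in% LETTERS)
  }
  mid <- paste0(core[-c(1L, npos)], subs[-c(1L, npos)], collapse = "")
  paste0(core[1L], "1", subs[1L], mid, core[npos], "1", subs[npos])
}

## One random molecule of a family (internal; RNG assumed seeded).
.randomFamilyMolecule <- function(family, hacTarget) {
  k <- max(2L, hacTarget)
  if (family == "aromatic") return(.randomAromaticSmiles(max(5L, hacTarget)))
  symbols <- rep("C", k)
  maxDeg <- rep(4L, k)
  nHet <- switch(family, alkane = 0L,
                 alcohol_ether = sample.int(min(2L, k - 1L), 1L),
                 amine = sample.int(min(2L, k - 1L), 1L))
  if (nHet > 0L) {
    het <- if (family == "amine") "N" else "O"
    idx <- sample.int(k, nHet)
    symbols[idx] <- het
    maxDeg[idx] <- if (het == "O") 2L else 3L
  }
  ## shuffle attachment order so heteroatoms land anywhere in the skeleton
  perm <- sample.int(k)
  .randomTreeSmiles(symbols[perm], maxDeg[perm])
}

#' Generate a synthetic query set
#'
#' Draws \code{n} molecules from weighted generator families (linear/branched
#' alkanes, alcohols/ethers, amines, substituted five- and six-membered
#' aromatics) with heavy atom counts uniform over \code{hacRange}.
#' Deterministic under \code{seed}; every emitted line parses. With default
#' weights and \code{n >= 100} the set spans well over ten property triplet
#' bins.
#'
#' @param n Number of molecules.
#' @param weights Named non-negative weights for families \code{alkane},
#'   \code{alcohol_ether}, \code{amine}, \code{aromatic}; must sum > 0.
#' @param hacRange Length-2 integer range of target heavy atom counts.
#' @param seed Integer seed.
#' @return data.frame with columns \code{smiles} and \code{id}
#'   (\code{q<i>}).
#' @export
generateQuerySet <- function(n, weights = c(alkane = 1, alcohol_ether = 1,
                                            amine = 1, aromatic = 1),
                             hacRange = c(6L, 14L), seed = 1L) {
  stopifnot(n >= 0, length(hacRange) == 2L, hacRange[1L] >= 2L,
            hacRange[1L] <= hacRange[2L])
  fam <- c("alkane", "alcohol_ether", "amine", "aromatic")
  w <- weights[fam]
  w[is.na(w)] <- 0
  if (any(w < 0) || sum(w) <= 0) stop("weights must be >= 0 and sum > 0")
  if (n == 0L)
    return(data.frame(smiles = character(0), id = character(0),
                      stringsAsFactors = FALSE))
  .withSeed(seed, {
    families <- sample(fam, n, replace = TRUE, prob = w / sum(w))
    hacs <- sample(seq(hacRange[1L], hacRange[2L]), n, replace = TRUE)
    smiles <- vapply(seq_len(n), function(i)
      .randomFamilyMolecule(families[i], hacs[i]), character(1))
    data.frame(smiles = smiles, id = paste0("q", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' Default reference scaffolds for the synthetic pipeline
#'
#' A fixed panel of drug-like small scaffolds (alcohols, ethers, amines,
#' substituted aromatics) spanning the same shingle families as the query
#' generator, each assigned a multiplicity; with \code{nReference} the
#' multiplicities are scaled so the corpus totals about that many molecules.
#'
#' @param nReference Approximate corpus size.
#' @return data.frame with columns \code{smiles}, \code{multiplicity}.
#' @export
defaultReferenceScaffolds <- function(nReference = 500L) {
  base <- c(
    "CCO", "CCN", "CCC", "CCCC", "CC(C)O", "CCOC", "CCCN", "CC(C)N",
    "CCCO", "CC(C)C", "CCCCO", "CCNCC", "COCCO", "CCOCC", "NCCO",
    "CC(O)CC", "CCCCC", "CC(C)CO", "CCCCN", "CNCCO",
    "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "Cc1ccncc1", "c1ccsc1",
    "c1ccoc1", "Oc1ccccc1", "Nc1ccccc1", "CCc1ccccc1", "COc1ccccc1",
    "Cc1cccc(C)c1", "Cc1ccc(O)cc1", "Cc1ccc(N)cc1", "CCOc1ccccc1",
    "Cc1cc[nH]c1", "CC(C)c1ccccc1", "OCc1ccccc1", "NCc1ccccc1",
    "CC(O)c1ccccc1", "CCNc1ccccc1"
  )
  mult <- pmax(1L, as.integer(round(nReference / length(base))))
  data.frame(smiles = base, multiplicity = mult, stringsAsFactors = FALSE)
}
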