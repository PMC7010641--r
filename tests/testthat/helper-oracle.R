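# Brute-force oracles and fixture helpers shared across the suite.

# Naive shingle oracle: for every atom, breadth-first collection of bonds to
# depth r (B1 = bonds incident to the root; B_{k+1} = B_k plus bonds incident
# to atoms covered by B_k), then canonical rooted rendering of the collected
# fragment. Independent of the engine's distance-filter enumeration.
# includeTruncated = TRUE also emits balls that stopped growing before the
# requested radius (used for the truncation-neutrality property).
# A radius is emitted only when at least one atom sits at topological distance
# exactly r from the root (balls that stopped growing stay frozen at their
# true radius; in particular the closing bond of an odd ring, which lies
# between two equally distant atoms, never extends a ball on its own).
oracleShingles <- function(mol, minRadius = 1L, maxRadius = 3L,
                           includeTruncated = FALSE) {
  b <- mol@bonds
  n <- nrow(mol@atoms)
  out <- character(0)
  for (a in seq_len(n)) {
    ballAtoms <- a
    ballBonds <- integer(0)
    for (r in seq_len(maxRadius)) {
      newBonds <- setdiff(which(b$from %in% ballAtoms | b$to %in% ballAtoms),
                          ballBonds)
      candAtoms <- union(ballAtoms, c(b$from[newBonds], b$to[newBonds]))
      grew <- length(candAtoms) > length(ballAtoms)
      if (grew) {
        ballBonds <- union(ballBonds, newBonds)
        ballAtoms <- candAtoms
      }
      if (r < minRadius) next
      if (!grew && !includeTruncated) next
      if (length(ballBonds) == 0L) next
      out <- c(out, canonicalFragment(mol, ballAtoms, a, ballBonds))
    }
  }
  sort(unique(out))
}

# Molecule-presence oracle for reference counts: for each shingle string, the
# number of corpus molecules whose shingle set contains it.
oraclePresenceCounts <- function(smiles) {
  sets <- lapply(smiles, function(s) {
    m <- tryCatch(parseMolecule(s), error = function(e) NULL)
    if (is.null(m)) character(0) else unique(extractShingles(m)$text)
  })
  tab <- table(unlist(sets))
  stats::setNames(as.integer(tab), names(tab))
}

# Rebuild a Molecule with atoms listed in a new order (graph unchanged).
permuteMolecule <- function(mol, ord) {
  n <- nrow(mol@atoms)
  stopifnot(length(ord) == n)
  newpos <- integer(n)
  newpos[ord] <- seq_len(n)
  atoms <- mol@atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol@bonds
  bonds$from <- newpos[bonds$from]
  bonds$to <- newpos[bonds$to]
  methods::new("Molecule", smiles = mol@smiles, id = mol@id,
               atoms = atoms, bonds = bonds)
}

# Deterministic panel of random small fixture molecules (<= 12 heavy atoms).
randomFixtureSmiles <- function(n, seed, hacRange = c(3L, 12L)) {
  generateQuerySet(n, hacRange = hacRange, seed = seed)$smiles
}

# A molecule with exactly four unique shingles (cyclobutene), used by the
# hand-computed scoring fixtures.
fourShingleMolecule <- function() parseMolecule("C1=CCC1")

# A frequency table over explicit entries, carrying the live engine tag.
makeTable <- function(entries, nMolecules = max(c(entries, 1L)),
                      minCount = 1L) {
  methods::new("ShingleFrequencyTable",
               entries = as.integer(entries) |>
                 stats::setNames(names(entries)),
               corpusName = "fixture", nMolecules = as.integer(nMolecules),
               nParseFailures = 0L, minCount = as.integer(minCount),
               minRadius = 1L, maxRadius = 3L,
               canonicalizationTag = canonicalizationTag())
}

# Random census fixture for allocator property tests.
randomCensus <- function(nbins, maxSize = 200L) {
  data.frame(
    hac = sample.int(17L, nbins, replace = TRUE),
    stereo_class = sample(0:5, nbins, replace = TRUE),
    hetero_class = sample(0:8, nbins, replace = TRUE),
    count = sample.int(maxSize, nbins, replace = TRUE)
  ) |> (\(d) d[!duplicated(d[1:3]), , drop = FALSE])() |>
    (\(d) { rownames(d) <- NULL; attr(d, "total") <- sum(d$count); d })()
}
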