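## SMILES parsing into a molecular graph.
##
## The engine reads a practical subset of the SMILES grammar: organic-subset
## atoms, bracket atoms with isotope / H count / charge / atom class, single,
## double, triple and aromatic bonds, branches, ring closures (incl. %nn) and
## dot-separated components. All stereochemistry tokens (@, @@, /, \) are
## parsed and discarded: shingle strings are stereochemistry-free by design.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

## standard valence lists for implicit hydrogen assignment
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S", "Se", "As")

.parse_error <- function(msg, smiles) {
  stop(structure(
    class = c("clscore_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error: %s in '%s'", msg, smiles),
         call = NULL, smiles = smiles)
  ))
}

## Tokenize one SMILES string into atom/bond vectors (internal).
.parseSmilesGraph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    .parse_error("empty input", if (length(smiles)) smiles else "")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  N <- length(chars)

  sym <- character(0); arom <- logical(0); charge <- integer(0)
  isotope <- integer(0); hexp <- integer(0); stereo <- logical(0)
  bfrom <- integer(0); bto <- integer(0); border <- integer(0)
  bexplicit <- character(0)   # "", "-", "=", "#", ":"

  prev <- NA_integer_
  stack <- integer(0)
  pending <- ""
  rings <- list()             # "digit" -> list(atom, code)

  addAtom <- function(s, ar, ch = 0L, iso = 0L, hx = -1L, st = FALSE) {
    sym[length(sym) + 1L] <<- s
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    isotope[length(isotope) + 1L] <<- iso
    hexp[length(hexp) + 1L] <<- hx
    stereo[length(stereo) + 1L] <<- st
    a <- length(sym)
    if (!is.na(prev)) addBond(prev, a, pending)
    pending <<- ""
    prev <<- a
    invisible(a)
  }

  addBond <- function(a, b, bondch) {
    if (a == b) .parse_error("self bond", smiles)
    ord <- switch(bondch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L, 1L)
    bfrom[length(bfrom) + 1L] <<- a
    bto[length(bto) + 1L] <<- b
    border[length(border) + 1L] <<- ord
    bexplicit[length(bexplicit) + 1L] <<- bondch
  }

  closeRing <- function(d) {
    key <- as.character(d)
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      rings[[key]] <<- NULL
      if (is.na(prev)) .parse_error("ring closure before any atom", smiles)
      ch1 <- op$code; ch2 <- pending
      bondch <- if (nzchar(ch1) && nzchar(ch2)) {
        if (ch1 != ch2) .parse_error("conflicting ring bond orders", smiles)
        ch1
      } else if (nzchar(ch1)) ch1 else ch2
      if (op$atom == prev) .parse_error("ring closure to same atom", smiles)
      addBond(op$atom, prev, bondch)
      pending <<- ""
    } else {
      if (is.na(prev)) .parse_error("ring opening before any atom", smiles)
      rings[[key]] <<- list(atom = prev, code = pending)
      pending <<- ""
    }
  }

  i <- 1L
  while (i <= N) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) break
    if (ch == "[") {
      j <- i
      while (j <= N && chars[j] != "]") j <- j + 1L
      if (j > N) .parse_error("unclosed bracket atom", smiles)
      body <- substr(smiles, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Za-z][a-z]?)(@@|@)?(H([0-9]*))?((\\+{1,3}|-{1,3})([0-9]*)?)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) .parse_error(sprintf("bad bracket atom [%s]", body), smiles)
      iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
      rawsym <- m[3]
      ar <- substr(rawsym, 1L, 1L) %in% letters
      s <- paste0(toupper(substr(rawsym, 1L, 1L)), substring(rawsym, 2L))
      if (!(s %in% .ELEMENTS)) .parse_error(sprintf("unknown element '%s'", s), smiles)
      if (ar && !(s %in% .AROMATIC_OK))
        .parse_error(sprintf("element '%s' cannot be aromatic", s), smiles)
      st <- nzchar(m[4])
      hx <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      ch_ <- 0L
      if (nzchar(m[7])) {
        sgn <- if (substr(m[8], 1L, 1L) == "+") 1L else -1L
        ch_ <- if (nzchar(m[9])) {
          if (nchar(m[8]) > 1L) .parse_error("bad charge", smiles)
          sgn * as.integer(m[9])
        } else sgn * nchar(m[8])
      }
      addAtom(s, ar, ch_, iso, hx, st)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < N && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        addAtom(two, FALSE)
        i <- i + 2L
      } else .parse_error(sprintf("unexpected token '%s'", two), smiles)
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      addAtom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      addAtom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending <- "-"          # directional bonds collapse to single
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) .parse_error("branch before any atom", smiles)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) .parse_error("unmatched ')'", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pending)) .parse_error("bond before '.'", smiles)
      prev <- NA_integer_
      i <- i + 1L
    } else if (ch %in% as.character(0:9)) {
      closeRing(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > N) .parse_error("truncated %nn ring closure", smiles)
      d <- suppressWarnings(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      if (is.na(d)) .parse_error("bad %nn ring closure", smiles)
      closeRing(d)
      i <- i + 3L
    } else {
      .parse_error(sprintf("unexpected character '%s'", ch), smiles)
    }
  }
  if (length(sym) == 0L) .parse_error("no atoms", smiles)
  if (length(rings) > 0L) .parse_error("unclosed ring bond", smiles)
  if (length(stack) > 0L) .parse_error("unmatched '('", smiles)
  if (nzchar(pending)) .parse_error("dangling bond", smiles)

  list(sym = sym, arom = arom, charge = charge, isotope = isotope,
       hexp = hexp, stereo = stereo,
       bfrom = bfrom, bto = bto, border = border, bexplicit = bexplicit)
}

## Enumerate simple rings of size 3..maxSize as atom-index vectors (internal).
.simpleRings <- function(n, bfrom, bto, maxSize = 7L) {
  if (length(bfrom) == 0L || n < 3L) return(list())
  adj <- vector("list", n)
  for (b in seq_along(bfrom)) {
    adj[[bfrom[b]]] <- c(adj[[bfrom[b]]], bto[b])
    adj[[bto[b]]] <- c(adj[[bto[b]]], bfrom[b])
  }
  rings <- list()
  seen <- character(0)
  ## DFS for paths start -> ... -> start of length 3..maxSize; anchor at the
  ## smallest atom index in the ring to bound duplication.
  for (start in seq_len(n)) {
    path <- integer(maxSize)
    dfs <- function(u, depth) {
      path[depth] <<- u
      for (v in adj[[u]]) {
        if (v == start && depth >= 3L) {
          ring <- path[seq_len(depth)]
          if (min(ring) == start) {
            key <- paste(sort(ring), collapse = ",")
            if (!(key %in% seen)) {
              seen <<- c(seen, key)
              rings[[length(rings) + 1L]] <<- ring
            }
          }
        } else if (depth < maxSize && v > start && !(v %in% path[seq_len(depth)])) {
          dfs(v, depth + 1L)
        }
      }
    }
    dfs(start, 1L)
  }
  rings
}

## Simplified Hueckel aromaticity perception over Kekule input (internal).
## Rings qualify when every member either carries a double bond whose partner
## is also a ring atom (1 pi electron) or is a lone-pair heteroatom (N, O, S,
## P; 2 pi electrons), and the electron sum is 4k + 2. Lowercase aromatic
## input is authoritative and such rings are skipped.
.perceiveAromaticity <- function(g, rings) {
  n <- length(g$sym)
  nb <- length(g$bfrom)
  barom <- logical(nb)
  ringAtoms <- if (length(rings)) unique(unlist(rings)) else integer(0)

  ## bond is in some ring?
  bondInRing <- logical(nb)
  if (length(rings)) {
    ringKeys <- unlist(lapply(rings, function(r) {
      rr <- c(r, r[1L])
      paste(pmin(rr[-1L], rr[-length(rr)]), pmax(rr[-1L], rr[-length(rr)]))
    }))
    bk <- paste(pmin(g$bfrom, g$bto), pmax(g$bfrom, g$bto))
    bondInRing <- bk %in% ringKeys
  }

  ## default (unmarked) bonds between two input-aromatic atoms are aromatic
  ## only when they sit in a ring; otherwise they are plain single bonds
  ## (e.g. the biphenyl linker).
  for (b in seq_len(nb)) {
    u <- g$bfrom[b]; v <- g$bto[b]
    if (g$arom[u] && g$arom[v] &&
        (g$bexplicit[b] == ":" || (g$bexplicit[b] == "" && bondInRing[b])))
      barom[b] <- TRUE
  }

  dbl <- lapply(seq_len(n), function(a) {
    bs <- which((g$bfrom == a | g$bto == a) & g$border == 2L & !barom)
    setdiff(c(g$bfrom[bs], g$bto[bs]), a)
  })
  trp <- vapply(seq_len(n), function(a)
    any((g$bfrom == a | g$bto == a) & g$border == 3L), logical(1))

  aromAtom <- g$arom
  for (ring in rings) {
    if (any(aromAtom[ring])) next
    pis <- 0L
    ok <- TRUE
    for (a in ring) {
      s <- g$sym[a]
      if (trp[a] || !(s %in% c("B", "C", "N", "O", "S", "P"))) { ok <- FALSE; break }
      partners <- dbl[[a]]
      if (length(partners) > 1L) { ok <- FALSE; break }
      if (length(partners) == 1L) {
        if (partners %in% ringAtoms) pis <- pis + 1L
        else { ok <- FALSE; break }  # exocyclic double bond blocks aromaticity
      } else {
        if (s %in% c("N", "O", "S", "P")) pis <- pis + 2L
        else { ok <- FALSE; break }  # saturated carbon
      }
    }
    if (ok && pis %% 4L == 2L) {
      aromAtom[ring] <- TRUE
      rr <- c(ring, ring[1L])
      e1 <- pmin(rr[-1L], rr[-length(rr)]); e2 <- pmax(rr[-1L], rr[-length(rr)])
      for (b in seq_len(nb)) {
        if (paste(pmin(g$bfrom[b], g$bto[b]), pmax(g$bfrom[b], g$bto[b])) %in%
            paste(e1, e2)) {
          barom[b] <- TRUE
          g$border[b] <- 1L
        }
      }
    }
  }
  g$arom <- aromAtom
  g$barom <- barom
  g
}

## Hydrogen count an unbracketed organic-subset atom would get from standard
## valence rules, for every atom (internal).
.valenceH <- function(g) {
  n <- length(g$sym)
  imp <- integer(n)
  for (a in seq_len(n)) {
    if (!(g$sym[a] %in% .ORGANIC)) next
    bs <- which(g$bfrom == a | g$bto == a)
    if (g$arom[a]) {
      conn <- length(bs)
      imp[a] <- switch(g$sym[a],
        C = max(0L, 3L - conn),
        B = max(0L, 2L - conn),
        0L)
    } else {
      D <- sum(g$border[bs])
      vals <- .VALENCES[[g$sym[a]]]
      v <- vals[vals >= D][1]
      imp[a] <- if (is.na(v)) 0L else as.integer(v - D)
    }
  }
  imp
}

## Resolve hydrogen counts and demote bracket atoms that no longer need a
## bracket once stereochemistry is stripped (internal): a neutral,
## isotope-free organic-subset atom whose explicit H count equals the
## standard-valence implicit value is rendered unbracketed, so stereoisomer
## inputs ([C@H], [C@@H]) and plain inputs yield identical shingle strings.
.resolveHydrogens <- function(g) {
  imp <- .valenceH(g)
  nH <- ifelse(g$hexp >= 0L, g$hexp, imp)
  demote <- g$hexp >= 0L & g$charge == 0L & g$isotope == 0L &
    g$sym %in% .ORGANIC & g$hexp == imp
  g$hexp[demote] <- -1L
  g$nH <- as.integer(nH)
  g
}
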