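#' Potential tetrahedral stereocenter count
#'
#' Counts atoms that can carry tetrahedral chirality, whether or not the input
#' assigned it: non-aromatic carbon or silicon (and positively charged
#' nitrogen) with four substituents (implicit hydrogens included), at most one
#' hydrogen, no multiple bonds, whose substituents fall in pairwise distinct
#' symmetry classes (see [symmetryClasses()]). Enumerated libraries carry
#' mostly unassigned centers, so potential centers are the default;
#' \code{mode = "assigned"} restricts to atoms that carried a \code{@} marker
#' in the input.
#'
#' @param mol A [Molecule-class].
#' @param mode "potential" (default) or "assigned".
#' @return Integer count.
#' @export
stereoCenterCount <- function(mol, mode = c("potential", "assigned")) {
  mode <- match.arg(mode)
  a <- mol@atoms; b <- mol@bonds
  n <- nrow(a)
  if (n == 0L) return(0L)
  ranks <- symmetryClasses(mol)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (a$aromatic[i]) next
    sym <- a$symbol[i]
    eligible <- sym %in% c("C", "Si") && a$charge[i] == 0L ||
      sym == "N" && a$charge[i] == 1L
    if (!eligible) next
    bs <- which(b$from == i | b$to == i)
    if (any(b$order[bs] > 1L) || any(b$aromatic[bs])) next
    nbrs <- setdiff(c(b$from[bs], b$to[bs]), i)
    h <- a$nH[i]
    if (length(nbrs) + h != 4L || h > 1L) next
    if (mode == "assigned" && !a$stereoMarked[i]) next
    if (anyDuplicated(ranks[nbrs]) == 0L) cnt <- cnt + 1L
  }
  cnt
}

#' Property triplet of a molecule
#'
#' The stratification key used for uniform sampling: heavy atom count,
#' stereocenter class and heteroatom class. High classes are merged:
#' stereocenter counts >= \code{stereoMerge} (default 5) collapse into one
#' class, heteroatom counts >= \code{heteroMerge} (default 8) into another,
#' i.e. stereo classes 0-4 plus ">=5" and heteroatom classes 0-7 plus ">=8".
#'
#' @param mol A [Molecule-class].
#' @param stereoMerge,heteroMerge Merge thresholds (defaults 5 and 8).
#' @param stereoMode Passed to [stereoCenterCount()].
#' @return Named integer vector \code{c(hac=, stereo_class=, hetero_class=)}.
#' @examples
#' computeTriplet(parseMolecule("CCO"))  # (3, 0, 1)
#' @export
computeTriplet <- function(mol, stereoMerge = 5L, heteroMerge = 8L,
                           stereoMode = "potential") {
  c(hac = hac(mol),
    stereo_class = min(stereoCenterCount(mol, stereoMode), as.integer(stereoMerge)),
    hetero_class = min(heteroAtomCount(mol), as.integer(heteroMerge)))
}

## Sortable bin key: lexicographic order on the key equals numeric order on
## the triplet (internal).
.binKey <- function(hac, stereo, hetero) {
  sprintf("%05d_%02d_%02d", hac, stereo, hetero)
}

#' Census of property triplet bins
#'
#' Single pass over SMILES records, counting occupancy of each (HAC,
#' stereocenter class, heteroatom class) bin. Empty bins are not materialized.
#' With \code{spillDir} given, every input line is appended verbatim to its
#' bin's file (\code{bin_<key>.smi}), enabling out-of-memory sampling; the
#' census/allocation/draw phases can be restarted from the spill directory.
#'
#' @param records Character vector of SMILES, a data.frame from
#'   [readSmilesFile()], or a file path (character of length 1 naming an
#'   existing file).
#' @param spillDir Optional directory for per-bin spill files.
#' @param stereoMerge,heteroMerge,stereoMode Passed to [computeTriplet()].
#' @param strict Abort on parse failure instead of skip-and-count.
#' @return A \code{data.frame} census with columns \code{hac},
#'   \code{stereo_class}, \code{hetero_class}, \code{count}, sorted by bin
#'   key, with attributes \code{total} and \code{parse_failures}.
#' @export
censusRecords <- function(records, spillDir = NULL, stereoMerge = 5L,
                          heteroMerge = 8L, stereoMode = "potential",
                          strict = FALSE) {
  if (is.character(records) && length(records) == 1L && file.exists(records))
    records <- readSmilesFile(records)
  if (is.character(records))
    records <- data.frame(smiles = records,
                          id = as.character(seq_along(records)),
                          text = records, stringsAsFactors = FALSE)
  if (is.null(records$text)) records$text <- records$smiles
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  spill <- !is.null(spillDir)
  if (spill) dir.create(spillDir, showWarnings = FALSE, recursive = TRUE)
  nFail <- 0L
  for (i in seq_len(nrow(records))) {
    mol <- tryCatch(parseMolecule(records$smiles[i], records$id[i]),
                    clscore_parse_error = function(e) e)
    if (inherits(mol, "clscore_parse_error")) {
      if (strict) stop(mol)
      nFail <- nFail + 1L
      next
    }
    tr <- computeTriplet(mol, stereoMerge, heteroMerge, stereoMode)
    key <- .binKey(tr[1L], tr[2L], tr[3L])
    cur <- counts[[key]]
    counts[[key]] <- if (is.null(cur)) 1L else cur + 1L
    if (spill)
      cat(records$text[i], "\n", sep = "",
          file = file.path(spillDir, paste0("bin_", key, ".smi")),
          append = TRUE)
  }
  keys <- sort(ls(counts, all.names = TRUE, sorted = FALSE), method = "radix")
  parts <- strsplit(keys, "_", fixed = TRUE)
  census <- data.frame(
    hac = as.integer(vapply(parts, `[[`, character(1), 1L)),
    stereo_class = as.integer(vapply(parts, `[[`, character(1), 2L)),
    hetero_class = as.integer(vapply(parts, `[[`, character(1), 3L)),
    count = vapply(keys, function(k) counts[[k]], integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(census, "total") <- sum(census$count)
  attr(census, "parse_failures") <- nFail
  census
}

#' Write / read a census TSV
#'
#' Columns \code{hac}, \code{stereo_class}, \code{hetero_class}, \code{count}.
#'
#' @param census A census data.frame from [censusRecords()].
#' @param path File path.
#' @return \code{writeCensus} returns \code{path} invisibly;
#'   \code{readCensus} returns the census data.frame.
#' @export
writeCensus <- function(census, path) {
  lines <- c("hac\tstereo_class\thetero_class\tcount",
             sprintf("%d\t%d\t%d\t%d", census$hac, census$stereo_class,
                     census$hetero_class, census$count))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCensus
#' @export
readCensus <- function(path) {
  census <- utils::read.delim(path, header = TRUE, sep = "\t",
                              colClasses = "integer")
  need <- c("hac", "stereo_class", "hetero_class", "count")
  if (!identical(names(census), need))
    stop("census format error: expected columns hac, stereo_class, hetero_class, count")
  attr(census, "total") <- sum(census$count)
  census
}

#' Iterative even allocation of a sampling target across bins
#'
#' Distributes \code{target} draws over occupied bins so that the sample is as
#' even as possible: bins are sorted by ascending size; iteratively, the
#' remaining target is divided by the number of remaining bins and every bin
#' no larger than that per-bin quota is taken entirely; once the smallest
#' remaining bin exceeds the quota, all remaining bins receive the same
#' (floored) quota, topped up by one extra draw per bin in ascending-size
#' order (ties broken by bin key) until the total equals
#' \code{min(target, total)}.
#'
#' @param census A census data.frame ([censusRecords()]).
#' @param target Total number of molecules to draw (>= 0).
#' @return The census with an added integer column \code{quota}; attribute
#'   \code{target} records the requested target.
#' @examples
#' census <- data.frame(hac = c(4L, 5L, 6L), stereo_class = 0L,
#'                      hetero_class = 0L, count = c(5L, 10L, 100L))
#' allocateUniform(census, 30)$quota  # 5, 10, 15
#' @export
allocateUniform <- function(census, target) {
  if (!(is.numeric(target) && length(target) == 1L && target >= 0))
    stop("target must be a single number >= 0")
  target <- as.integer(target)
  n <- nrow(census)
  quota <- integer(n)
  if (n > 0L && target > 0L) {
    key <- .binKey(census$hac, census$stereo_class, census$hetero_class)
    ord <- order(census$count, key, method = "radix")
    sizes <- census$count[ord]
    remaining <- min(target, sum(sizes))
    taken <- logical(n)
    q <- quota[ord]
    repeat {
      left <- which(!taken)
      if (length(left) == 0L) break
      per <- remaining / length(left)
      small <- left[sizes[left] <= per]
      if (length(small) == 0L) break
      q[small] <- sizes[small]
      remaining <- remaining - sum(sizes[small])
      taken[small] <- TRUE
    }
    left <- which(!taken)
    if (length(left) > 0L) {
      base <- remaining %/% length(left)
      extra <- remaining - base * length(left)
      q[left] <- base
      if (extra > 0L) q[left[seq_len(extra)]] <- base + 1L
    }
    quota[ord] <- q
  }
  out <- census
  out$quota <- quota
  attr(out, "target") <- target
  attr(out, "total") <- sum(census$count)
  out
}

## Deterministic per-bin seed derived from the run seed and the bin key
## (internal). Stable across platforms and runs; result in [0, 2^31 - 2].
.binSeed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

## Evaluate expr under a private RNG seeded with seed, restoring the caller's
## RNG state (internal).
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

## Reservoir sample of k elements from x, uniform without replacement, in
## draw order (internal). Assumes the RNG is already seeded.
.reservoir <- function(x, k) {
  n <- length(x)
  if (k >= n) return(x)
  if (k == 0L) return(x[0L])
  res <- x[seq_len(k)]
  for (i in (k + 1L):n) {
    j <- sample.int(i, 1L)
    if (j <= k) res[j] <- x[i]
  }
  res
}

#' Draw a seeded uniform sample according to an allocation
#'
#' Per bin, exactly \code{quota} records are drawn uniformly without
#' replacement by reservoir sampling under a bin-specific seed derived
#' deterministically from \code{seed} and the bin key, so repeat runs with the
#' same seed are byte-identical. Output order: bins in bin-key order, records
#' in draw order.
#'
#' @param allocation An allocation data.frame from [allocateUniform()].
#' @param seed Integer run seed.
#' @param spillDir Directory of per-bin spill files written by
#'   [censusRecords()]; either this or \code{records} must be given.
#' @param records Alternative in-memory input: character vector of record
#'   lines (SMILES with optional id), binned by parsing each line.
#' @param stereoMerge,heteroMerge,stereoMode Used to bin \code{records}; must
#'   match the census parameters.
#' @return Character vector of selected record lines.
#' @export
drawSample <- function(allocation, seed, spillDir = NULL, records = NULL,
                       stereoMerge = 5L, heteroMerge = 8L,
                       stereoMode = "potential") {
  stopifnot(!is.null(allocation$quota))
  key <- .binKey(allocation$hac, allocation$stereo_class,
                 allocation$hetero_class)
  ord <- order(key, method = "radix")
  if (is.null(spillDir) == is.null(records))
    stop("supply exactly one of spillDir or records")
  binLines <- function(k) {
    if (!is.null(spillDir)) {
      f <- file.path(spillDir, paste0("bin_", k, ".smi"))
      if (!file.exists(f)) character(0) else readLines(f, warn = FALSE)
    } else {
      grouped[[k]]
    }
  }
  if (!is.null(records)) {
    grouped <- new.env(parent = emptyenv(), hash = TRUE)
    for (line in records) {
      sm <- strsplit(trimws(line), "\\s+")[[1]][1]
      mol <- tryCatch(parseMolecule(sm), clscore_parse_error = function(e) NULL)
      if (is.null(mol)) next
      tr <- computeTriplet(mol, stereoMerge, heteroMerge, stereoMode)
      k <- .binKey(tr[1L], tr[2L], tr[3L])
      grouped[[k]] <- c(grouped[[k]], line)
    }
  }
  out <- character(0)
  for (i in ord) {
    q <- allocation$quota[i]
    if (q == 0L) next
    lines <- binLines(key[i])
    if (length(lines) < q)
      stop(sprintf(
        "allocation/census mismatch: bin %s has %d records but quota %d",
        key[i], length(lines), q))
    sel <- .withSeed(.binSeed(seed, key[i]), .reservoir(lines, q))
    out <- c(out, sel)
  }
  out
}
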