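#' ShingleFrequencyTable: shingle frequencies of a reference corpus
#'
#' Maps canonical shingle strings to the number of corpus molecules containing
#' them at least once (molecule-level presence counts, not total occurrences:
#' within one molecule every shingle is uniquely counted). Entries below the
#' minimum-occurrence cutoff are dropped at build time. Provenance metadata
#' records the corpus, the cutoff, the radii and the canonicalization tag;
#' scoring refuses tables whose tag differs from the running engine's.
#'
#' @slot entries Named integer vector: shingle string -> molecule count,
#'   keys sorted bytewise.
#' @slot corpusName Character label of the corpus.
#' @slot nMolecules Number of successfully parsed corpus molecules.
#' @slot nParseFailures Number of skipped unparseable records.
#' @slot minCount Minimum-occurrence cutoff applied (the reference pipeline
#'   used 100).
#' @slot minRadius,maxRadius Shingle radii used.
#' @slot canonicalizationTag Engine convention tag, see
#'   [canonicalizationTag()].
#'
#' @seealso [buildReferenceTable()], [lookupShingle()], [saveShingleTable()]
#' @export
setClass("ShingleFrequencyTable", representation(
  entries = "integer",
  corpusName = "character",
  nMolecules = "integer",
  nParseFailures = "integer",
  minCount = "integer",
  minRadius = "integer",
  maxRadius = "integer",
  canonicalizationTag = "character"
))

setValidity("ShingleFrequencyTable", function(object) {
  e <- object@entries
  if (length(e)) {
    if (is.null(names(e)) || any(!nzchar(names(e))))
      return("all entries must be named by shingle strings")
    if (anyDuplicated(names(e))) return("duplicate shingle keys")
    if (any(e < object@minCount))
      return("entries below the minCount cutoff are not allowed")
    if (object@nMolecules > 0L && any(e > object@nMolecules))
      return("presence counts cannot exceed the corpus size")
  }
  TRUE
})

setMethod("show", "ShingleFrequencyTable", function(object) {
  cat("ShingleFrequencyTable\n")
  cat(sprintf("  corpus: %s (%d molecules, %d parse failures)\n",
              object@corpusName, object@nMolecules, object@nParseFailures))
  cat(sprintf("  %d shingles at count >= %d, radii %d-%d\n",
              length(object@entries), object@minCount, object@minRadius,
              object@maxRadius))
  cat(sprintf("  tag: %s\n", object@canonicalizationTag))
  invisible(object)
})

#' @describeIn ShingleFrequencyTable-class Number of stored shingles.
#' @param x A \code{ShingleFrequencyTable}.
#' @export
setMethod("length", "ShingleFrequencyTable", function(x) length(x@entries))

#' Build a shingle frequency table from a reference corpus
#'
#' Decomposes every corpus molecule into its unique shingle set (radii
#' \code{minRadius}..\code{maxRadius}) and counts, for each shingle, the
#' number of molecules containing it; a molecule increments a shingle at most
#' once. Shingles whose final count falls below \code{minCount} are dropped.
#' Unparseable records are skipped and counted (or abort in strict mode).
#'
#' @param smiles Character vector of SMILES, or a data.frame with columns
#'   \code{smiles} and \code{id} as returned by [readSmilesFile()].
#' @param minCount Minimum molecule count for a shingle to be stored
#'   (default 100, the reference pipeline's cutoff).
#' @param corpusName Label stored in the table metadata.
#' @param minRadius,maxRadius Shingle radii (defaults 1 and 3).
#' @param dedupe If TRUE, canonicalize and deduplicate corpus structures
#'   before counting; by default exact duplicates each contribute, mirroring
#'   raw corpus statistics.
#' @param strict Abort on the first unparseable record instead of skipping.
#' @return A [ShingleFrequencyTable-class].
#' @examples
#' tab <- buildReferenceTable(rep("CCO", 150), minCount = 100)
#' length(tab)   # ethanol has 5 unique shingles
#' @export
buildReferenceTable <- function(smiles, minCount = 100L,
                                corpusName = "reference",
                                minRadius = 1L, maxRadius = 3L,
                                dedupe = FALSE, strict = FALSE) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  if (!(is.numeric(minCount) && length(minCount) == 1L && minCount >= 1))
    stop("minCount must be a single integer >= 1")
  minCount <- as.integer(minCount)
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  nOk <- 0L
  nFail <- 0L
  seen <- character(0)
  for (s in smiles) {
    mol <- tryCatch(parseMolecule(s), clscore_parse_error = function(e) e)
    if (inherits(mol, "clscore_parse_error")) {
      if (strict) stop(mol)
      nFail <- nFail + 1L
      next
    }
    if (dedupe) {
      can <- canonicalSmiles(mol)
      if (can %in% seen) next
      seen <- c(seen, can)
    }
    nOk <- nOk + 1L
    sh <- extractShingles(mol, minRadius, maxRadius)$text
    for (t in sh) {
      cur <- counts[[t]]
      counts[[t]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  if (nOk == 0L && length(smiles) > 0L)
    warning("no corpus record parsed successfully; table is empty")
  keys <- sort(ls(counts, all.names = TRUE, sorted = FALSE), method = "radix")
  vals <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- vals >= minCount
  entries <- vals[keep]
  names(entries) <- keys[keep]
  methods::new("ShingleFrequencyTable",
               entries = entries,
               corpusName = corpusName,
               nMolecules = nOk,
               nParseFailures = nFail,
               minCount = minCount,
               minRadius = as.integer(minRadius),
               maxRadius = as.integer(maxRadius),
               canonicalizationTag = canonicalizationTag())
}

#' Look up shingle counts
#'
#' Returns the stored molecule count for each shingle string, or \code{NA}
#' for shingles absent from the table (absence is explicit, never a zero
#' count: stored counts are always >= the table's cutoff).
#'
#' @param table A [ShingleFrequencyTable-class].
#' @param shingleText Character vector of canonical shingle strings.
#' @return Integer vector, \code{NA} where absent.
#' @export
lookupShingle <- function(table, shingleText) {
  stopifnot(methods::is(table, "ShingleFrequencyTable"))
  unname(table@entries[match(shingleText, names(table@entries))])
}

.TABLE_META_KEYS <- c("corpus_name", "n_molecules", "n_parse_failures",
                      "min_count", "min_radius", "max_radius",
                      "canonicalization_tag")

#' Save / load a shingle frequency table
#'
#' Bit-exact UTF-8 text format: one \code{#key<TAB>value} header line per
#' metadata field in fixed order (corpus_name, n_molecules, n_parse_failures,
#' min_count, min_radius, max_radius, canonicalization_tag), then one
#' \code{shingle<TAB>count} line per entry with keys in bytewise sorted
#' order. The round trip is lossless.
#'
#' @param table A [ShingleFrequencyTable-class].
#' @param path File path.
#' @return \code{saveShingleTable} returns \code{path} invisibly;
#'   \code{loadShingleTable} returns the table.
#' @export
saveShingleTable <- function(table, path) {
  stopifnot(methods::is(table, "ShingleFrequencyTable"))
  meta <- c(table@corpusName, table@nMolecules, table@nParseFailures,
            table@minCount, table@minRadius, table@maxRadius,
            table@canonicalizationTag)
  hdr <- sprintf("#%s\t%s", .TABLE_META_KEYS, meta)
  keys <- sort(names(table@entries), method = "radix")
  body <- if (length(keys)) sprintf("%s\t%d", keys, table@entries[keys])
          else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname saveShingleTable
#' @export
loadShingleTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ishdr <- grepl("^#", lines)
  hdr <- lines[ishdr]
  body <- lines[!ishdr]
  toks <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  keys <- vapply(toks, `[[`, character(1), 1L)
  for (k in .TABLE_META_KEYS)
    if (!(k %in% keys))
      stop(sprintf("shingle table format error: missing '#%s' header", k))
  val <- function(k) {
    v <- toks[[match(k, keys)]]
    if (length(v) < 2L) "" else v[[2L]]
  }
  body <- body[nzchar(body)]
  bt <- strsplit(body, "\t", fixed = TRUE)
  if (length(bt) && any(lengths(bt) != 2L))
    stop("shingle table format error: malformed entry line")
  entries <- if (length(bt)) {
    cnt <- suppressWarnings(as.integer(vapply(bt, `[[`, character(1), 2L)))
    if (anyNA(cnt)) stop("shingle table format error: non-integer count")
    stats::setNames(cnt, vapply(bt, `[[`, character(1), 1L))
  } else stats::setNames(integer(0), character(0))
  methods::new("ShingleFrequencyTable",
               entries = entries,
               corpusName = val("corpus_name"),
               nMolecules = as.integer(val("n_molecules")),
               nParseFailures = as.integer(val("n_parse_failures")),
               minCount = as.integer(val("min_count")),
               minRadius = as.integer(val("min_radius")),
               maxRadius = as.integer(val("max_radius")),
               canonicalizationTag = val("canonicalization_tag"))
}
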