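#' ScoreBreakdown: per-molecule CLscore detail
#'
#' The CLscore of a molecule with N unique shingles, of which m are present in
#' the reference table with molecule counts f, is
#' \deqn{CLscore = (1/N) \sum_{i=1}^{m} \log_{10} f_i}
#' Unmatched shingles contribute nothing to the sum but still count in N.
#' Molecules with no shingles (a single heavy atom) score 0 by definition.
#' Since stored counts are >= 1, CLscore is always >= 0.
#'
#' @slot nShingles N, total unique shingles of the molecule.
#' @slot nMatched m, shingles found in the table.
#' @slot logSum Sum of log10 counts over matched shingles.
#' @slot clscore The final score.
#' @seealso [scoreMolecule()]
#' @export
setClass("ScoreBreakdown", representation(
  nShingles = "integer",
  nMatched = "integer",
  logSum = "numeric",
  clscore = "numeric"
))

setValidity("ScoreBreakdown", function(object) {
  if (object@nMatched < 0L || object@nMatched > object@nShingles)
    return("require 0 <= nMatched <= nShingles")
  if (object@clscore < 0) return("CLscore is non-negative by construction")
  TRUE
})

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("CLscore %.6f (N = %d shingles, m = %d matched, log-sum %.6f)\n",
              object@clscore, object@nShingles, object@nMatched,
              object@logSum))
  invisible(object)
})

#' @describeIn ScoreBreakdown-class The CLscore value.
#' @param x A \code{ScoreBreakdown}.
#' @export
setGeneric("clscore", function(x) standardGeneric("clscore"))

#' @rdname ScoreBreakdown-class
#' @export
setMethod("clscore", "ScoreBreakdown", function(x) x@clscore)

.checkTag <- function(table) {
  if (!identical(table@canonicalizationTag, canonicalizationTag()))
    stop(sprintf(
      paste0("canonicalization tag mismatch: table built under '%s', ",
             "engine is '%s'; rebuild the table with this engine"),
      table@canonicalizationTag, canonicalizationTag()))
}

#' Score one molecule against a reference table
#'
#' Extracts the molecule's unique shingles at the table's radii, looks each up
#' in the table, sums log10 of the matched counts and divides by the total
#' number of unique shingles.
#'
#' @param mol A [Molecule-class].
#' @param table A [ShingleFrequencyTable-class] built under the same
#'   canonicalization tag (enforced).
#' @return A [ScoreBreakdown-class].
#' @examples
#' tab <- buildReferenceTable(rep("CCO", 150))
#' scoreMolecule(parseMolecule("CCO"), tab)
#' @export
scoreMolecule <- function(mol, table) {
  stopifnot(methods::is(mol, "Molecule"),
            methods::is(table, "ShingleFrequencyTable"))
  .checkTag(table)
  sh <- extractShingles(mol, table@minRadius, table@maxRadius)$text
  n <- length(sh)
  f <- lookupShingle(table, sh)
  m <- sum(!is.na(f))
  ls <- sum(log10(f[!is.na(f)]))
  methods::new("ScoreBreakdown",
               nShingles = n, nMatched = as.integer(m),
               logSum = ls,
               clscore = if (n > 0L) ls / n else 0)
}

#' Score a stream of SMILES records
#'
#' Order-preserving scoring of many records with optional cutoff filtering:
#' with \code{cutoff} given, only records with CLscore >= cutoff (inclusive)
#' are emitted. Unparseable records are skipped and counted, or abort in
#' strict mode.
#'
#' @param records Character vector of SMILES or a data.frame with columns
#'   \code{smiles} and \code{id} ([readSmilesFile()] output).
#' @param table A [ShingleFrequencyTable-class].
#' @param cutoff NULL (no filtering) or a single number >= 0.
#' @param strict Abort on the first parse failure.
#' @return A list with \code{results} (data.frame: smiles, id, clscore,
#'   n_shingles, n_matched) and counters \code{scored}, \code{passed},
#'   \code{parse_failures}.
#' @export
scoreRecords <- function(records, table, cutoff = NULL, strict = FALSE) {
  stopifnot(methods::is(table, "ShingleFrequencyTable"))
  .checkTag(table)
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
    if (cutoff < 0) stop("cutoff must be NULL or >= 0")
  }
  if (is.character(records))
    records <- data.frame(smiles = records, id = as.character(seq_along(records)),
                          stringsAsFactors = FALSE)
  n <- nrow(records)
  smiles <- character(n); id <- character(n)
  sc <- numeric(n); ns <- integer(n); nm <- integer(n)
  k <- 0L
  nFail <- 0L
  for (i in seq_len(n)) {
    mol <- tryCatch(parseMolecule(records$smiles[i], records$id[i]),
                    clscore_parse_error = function(e) e)
    if (inherits(mol, "clscore_parse_error")) {
      if (strict) stop(mol)
      nFail <- nFail + 1L
      next
    }
    br <- scoreMolecule(mol, table)
    k <- k + 1L
    smiles[k] <- records$smiles[i]; id[k] <- records$id[i]
    sc[k] <- br@clscore; ns[k] <- br@nShingles; nm[k] <- br@nMatched
  }
  res <- data.frame(smiles = smiles[seq_len(k)], id = id[seq_len(k)],
                    clscore = sc[seq_len(k)], n_shingles = ns[seq_len(k)],
                    n_matched = nm[seq_len(k)], stringsAsFactors = FALSE)
  scored <- k
  if (!is.null(cutoff)) res <- res[res$clscore >= cutoff, , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, scored = scored, passed = nrow(res),
       parse_failures = nFail)
}

#' Score a SMILES file to a TSV
#'
#' File-level wrapper around [scoreRecords()]: reads \code{inPath}, scores
#' against \code{table}, optionally filters at \code{cutoff}, and writes a TSV
#' with columns smiles, id, clscore (6 decimals), n_shingles, n_matched.
#'
#' @inheritParams scoreRecords
#' @param inPath Input SMILES file.
#' @param outPath Output TSV path, or NULL to skip writing.
#' @return Invisibly, the [scoreRecords()] result list.
#' @export
scoreFile <- function(inPath, table, outPath = NULL, cutoff = NULL,
                      strict = FALSE) {
  out <- scoreRecords(readSmilesFile(inPath), table, cutoff = cutoff,
                      strict = strict)
  if (!is.null(outPath)) {
    df <- out$results
    lines <- c("smiles\tid\tclscore\tn_shingles\tn_matched",
               sprintf("%s\t%s\t%.6f\t%d\t%d", df$smiles, df$id, df$clscore,
                       df$n_shingles, df$n_matched))
    writeLines(lines, outPath)
  }
  invisible(out)
}
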