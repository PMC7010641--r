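#' Run the full pipeline on synthetic fixtures
#'
#' End-to-end smoke pipeline: generate (or load) a reference corpus, build the
#' shingle frequency table, score and filter a query set, bin the survivors
#' into property triplet bins with spill files, allocate a uniform sample and
#' draw it. Artifacts (\code{ref.smi}, \code{table.tsv}, \code{query.smi},
#' \code{scored.tsv}, \code{passing.smi}, \code{census.tsv},
#' \code{sample.smi}, \code{manifest.json}) are written under \code{outDir};
#' a stage that fails leaves its artifact with a \code{.partial} suffix.
#'
#' @param outDir Output directory (created if needed).
#' @param nReference Approximate synthetic reference corpus size (ignored when
#'   \code{refFile} is given).
#' @param nQuery Synthetic query set size (ignored when \code{queryFile} is
#'   given).
#' @param minCount Table cutoff (see [buildReferenceTable()]). The reference
#'   pipeline used 100; the synthetic default 10 keeps small corpora
#'   informative.
#' @param cutoff CLscore cutoff. A number filters at that value (the reference
#'   pipeline used 3.3); \code{cutoffPercentile} instead derives the cutoff
#'   from the empirical score distribution of the query set.
#' @param cutoffPercentile If not NULL (and \code{cutoff} is NULL), the cutoff
#'   is the empirical \code{cutoffPercentile} quantile of the query scores,
#'   e.g. 0.6 retains roughly the top 40 percent.
#' @param target Number of molecules to sample.
#' @param seed Integer seed governing corpus shuffling, query generation and
#'   sampling.
#' @param refFile,queryFile Optional SMILES files overriding the synthetic
#'   generators.
#' @return Invisibly, a manifest list with all parameters, derived values and
#'   stage counters (also written as \code{manifest.json}).
#' @export
runEndToEnd <- function(outDir, nReference = 500L, nQuery = 5000L,
                        minCount = 10L, cutoff = NULL,
                        cutoffPercentile = NULL, target = 500L, seed = 42L,
                        refFile = NULL, queryFile = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, file, expr) {
    partial <- paste0(file, ".partial")
    ok <- FALSE
    on.exit(if (!ok && file.exists(file)) file.rename(file, partial))
    res <- expr
    ok <- TRUE
    res
  }

  refPath <- file.path(outDir, "ref.smi")
  if (is.null(refFile)) {
    refLines <- generateReferenceCorpus(defaultReferenceScaffolds(nReference),
                                        shuffleSeed = seed)
    writeLines(refLines, refPath)
  } else {
    file.copy(refFile, refPath, overwrite = TRUE)
    refLines <- readSmilesFile(refPath)$smiles
  }

  tablePath <- file.path(outDir, "table.tsv")
  table <- stage("build-ref", tablePath, {
    t <- buildReferenceTable(refLines, minCount = minCount,
                             corpusName = basename(refPath))
    saveShingleTable(t, tablePath)
    t
  })

  queryPath <- file.path(outDir, "query.smi")
  if (is.null(queryFile)) {
    qs <- generateQuerySet(nQuery, seed = seed + 1L)
    writeLines(paste(qs$smiles, qs$id), queryPath)
  } else {
    file.copy(queryFile, queryPath, overwrite = TRUE)
  }

  scoredPath <- file.path(outDir, "scored.tsv")
  scored <- stage("score", scoredPath,
                  scoreFile(queryPath, table, outPath = scoredPath))
  if (is.null(cutoff)) {
    if (!is.null(cutoffPercentile)) {
      stopifnot(cutoffPercentile >= 0, cutoffPercentile <= 1)
      cutoff <- unname(stats::quantile(scored$results$clscore,
                                       probs = cutoffPercentile, type = 1))
    } else {
      cutoff <- 0
    }
  }
  pass <- scored$results[scored$results$clscore >= cutoff, , drop = FALSE]
  passingPath <- file.path(outDir, "passing.smi")
  writeLines(paste(pass$smiles, pass$id), passingPath)

  spillDir <- file.path(outDir, "bins")
  unlink(spillDir, recursive = TRUE)
  censusPath <- file.path(outDir, "census.tsv")
  census <- stage("bin", censusPath, {
    cs <- censusRecords(readSmilesFile(passingPath), spillDir = spillDir)
    writeCensus(cs, censusPath)
    cs
  })

  allocation <- allocateUniform(census, target)
  samplePath <- file.path(outDir, "sample.smi")
  sampled <- stage("sample", samplePath, {
    sel <- drawSample(allocation, seed = seed, spillDir = spillDir)
    writeLines(sel, samplePath)
    sel
  })

  manifest <- list(
    tool = "clscore",
    version = as.character(utils::packageVersion("clscore")),
    canonicalization_tag = canonicalizationTag(),
    parameters = list(
      n_reference = if (is.null(refFile)) nReference else NA_integer_,
      n_query = if (is.null(queryFile)) nQuery else NA_integer_,
      min_count = minCount, cutoff = cutoff,
      cutoff_percentile = cutoffPercentile,
      target = target, seed = seed,
      ref_file = refFile, query_file = queryFile
    ),
    counters = list(
      reference_molecules = table@nMolecules,
      reference_parse_failures = table@nParseFailures,
      table_shingles = length(table@entries),
      queries_scored = scored$scored,
      query_parse_failures = scored$parse_failures,
      passing = nrow(pass),
      retained_fraction = if (scored$scored > 0)
        nrow(pass) / scored$scored else 0,
      occupied_bins = nrow(census),
      sampled = length(sampled)
    )
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
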