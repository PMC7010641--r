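test_that("reference corpus generation yields exact downstream counts", {
  # single scaffold: 150 ethanol lines, 5 table entries of count 150
  lines <- generateReferenceCorpus(
    data.frame(smiles = "CCO", multiplicity = 150L), shuffleSeed = 4)
  expect_length(lines, 150L)
  expect_true(all(lines == "CCO"))
  tab <- buildReferenceTable(lines, minCount = 100)
  expect_equal(length(tab), 5L)
  expect_true(all(tab@entries == 150L))

  # below the cutoff nothing survives
  l99 <- generateReferenceCorpus(
    data.frame(smiles = "CCO", multiplicity = 99L), shuffleSeed = 4)
  expect_equal(length(buildReferenceTable(l99, minCount = 100)), 0L)

  # shared shingles accumulate across scaffolds: ethanol + ethylamine at 120
  # each; the shared carbon-rooted shingles count 240, specific ones 120
  spec <- data.frame(smiles = c("CCO", "CCN"), multiplicity = c(120L, 120L))
  tab2 <- buildReferenceTable(generateReferenceCorpus(spec, 11), minCount = 100)
  shared <- intersect(oracleShingles(parseMolecule("CCO")),
                      oracleShingles(parseMolecule("CCN")))
  specific <- setdiff(oracleShingles(parseMolecule("CCO")), shared)
  expect_true(length(shared) > 0L && length(specific) > 0L)
  expect_true(all(lookupShingle(tab2, shared) == 240L))
  expect_true(all(lookupShingle(tab2, specific) == 120L))

  # invalid scaffolds error before any emission
  expect_error(generateReferenceCorpus(
    data.frame(smiles = c("CCO", "C1CC"), multiplicity = 1L)),
    class = "clscore_parse_error")
  expect_error(generateReferenceCorpus(
    data.frame(smiles = "CCO", multiplicity = 0L)), "multiplicities")
})

test_that("corpus shuffling is deterministic and leaves the RNG alone", {
  spec <- data.frame(smiles = c("CCO", "CCN", "CCC"),
                     multiplicity = c(5L, 3L, 2L))
  a <- generateReferenceCorpus(spec, shuffleSeed = 21)
  b <- generateReferenceCorpus(spec, shuffleSeed = 21)
  expect_identical(a, b)
  expect_identical(sort(a), sort(rep(spec$smiles, spec$multiplicity)))
  set.seed(2); x <- runif(1)
  set.seed(2); invisible(generateReferenceCorpus(spec, 21)); y <- runif(1)
  expect_identical(x, y)
})

test_that("query sets are deterministic, parseable and span many bins", {
  q1 <- generateQuerySet(100, seed = 1)
  q2 <- generateQuerySet(100, seed = 1)
  expect_identical(q1, q2)
  expect_equal(nrow(generateQuerySet(0, seed = 1)), 0L)

  q <- generateQuerySet(300, seed = 6)
  expect_equal(nrow(q), 300L)
  mols <- lapply(q$smiles, function(s)
    tryCatch(parseMolecule(s), error = function(e) NULL))
  expect_false(any(vapply(mols, is.null, logical(1))))
  cs <- censusRecords(q$smiles)
  expect_gte(nrow(cs), 10L)
  expect_error(generateQuerySet(10, weights = c(alkane = -1)), "weights")
})

test_that("the end-to-end pipeline produces consistent artifacts", {
  outDir <- withr::local_tempdir()
  man <- runEndToEnd(outDir, nReference = 150L, nQuery = 600L,
                     minCount = 5L, cutoffPercentile = 0.5, target = 120L,
                     seed = 3L)
  expect_true(all(file.exists(file.path(outDir,
    c("ref.smi", "table.tsv", "query.smi", "scored.tsv", "passing.smi",
      "census.tsv", "sample.smi", "manifest.json")))))
  expect_equal(man$counters$sampled, 120L)
  expect_equal(man$counters$queries_scored, 600L)
  # sampled records come from the passing set
  sampled <- readLines(file.path(outDir, "sample.smi"))
  passing <- readLines(file.path(outDir, "passing.smi"))
  expect_true(all(sampled %in% passing))
  expect_false(anyDuplicated(sampled) > 0L)
  # the stored table reloads to the one used
  tab <- loadShingleTable(file.path(outDir, "table.tsv"))
  expect_equal(length(tab), man$counters$table_shingles)
  # census totals match the passing count
  cs <- readCensus(file.path(outDir, "census.tsv"))
  expect_equal(attr(cs, "total"), man$counters$passing)

  # cutoff 0 with a target covering everything keeps all parseable queries
  outDir2 <- withr::local_tempdir()
  man2 <- runEndToEnd(outDir2, nReference = 60L, nQuery = 80L, minCount = 2L,
                      cutoff = 0, target = 10000L, seed = 5L)
  expect_equal(man2$counters$passing, 80L)
  expect_equal(man2$counters$sampled, 80L)

  # a cutoff above every observed score gives an empty but valid result
  outDir3 <- withr::local_tempdir()
  man3 <- runEndToEnd(outDir3, nReference = 60L, nQuery = 50L, minCount = 2L,
                      cutoff = 99, target = 10L, seed = 5L)
  expect_equal(man3$counters$passing, 0L)
  expect_equal(man3$counters$sampled, 0L)
})

test_that("the CLI wraps the pipeline stages", {
  dir <- withr::local_tempdir()
  ref <- file.path(dir, "ref.smi")
  writeLines(generateReferenceCorpus(
    data.frame(smiles = c("CCO", "CCN"), multiplicity = 60L), 1), ref)
  tablePath <- file.path(dir, "table.tsv")
  expect_equal(suppressMessages(clscoreCLI(
    c("build-ref", "--in", ref, "--out", tablePath, "--min-count", "50"))), 0L)
  expect_true(file.exists(tablePath))

  q <- file.path(dir, "q.smi")
  writeLines(c("CCO a", "c1ccccc1 b"), q)
  scored <- file.path(dir, "scored.tsv")
  expect_equal(suppressMessages(clscoreCLI(
    c("score", "--in", q, "--table", tablePath, "--out", scored,
      "--cutoff", "0.5"))), 0L)
  expect_equal(length(readLines(scored)), 2L)  # header + ethanol

  censusPath <- file.path(dir, "census.tsv")
  spill <- file.path(dir, "bins")
  expect_equal(suppressMessages(clscoreCLI(
    c("bin", "--in", q, "--spill-dir", spill, "--census", censusPath))), 0L)
  samplePath <- file.path(dir, "sample.smi")
  expect_equal(suppressMessages(clscoreCLI(
    c("sample", "--spill-dir", spill, "--census", censusPath,
      "--target", "1", "--seed", "4", "--out", samplePath))), 0L)
  expect_equal(length(readLines(samplePath)), 1L)
  expect_equal(suppressMessages(clscoreCLI(c("nonsense"))), 1L)
})
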