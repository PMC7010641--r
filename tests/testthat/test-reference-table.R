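test_that("presence counting is per molecule and the cutoff drops rare shingles", {
  # 150 copies of ethanol at cutoff 100: all 5 ethanol shingles, count 150
  tab <- buildReferenceTable(rep("CCO", 150), minCount = 100)
  expect_equal(length(tab), 5L)
  expect_true(all(tab@entries == 150L))
  expect_identical(sort(names(tab@entries)), oracleShingles(parseMolecule("CCO")))

  # 99 copies fall below the cutoff
  expect_equal(length(buildReferenceTable(rep("CCO", 99), minCount = 100)), 0L)

  # propane has two terminal roots emitting the same 2-atom shingle; unique
  # counting stores 100, not 200
  tab3 <- buildReferenceTable(rep("CCC", 100), minCount = 1)
  expect_equal(unname(tab3@entries["CC"]), 100L)
  expect_true(all(tab3@entries == 100L))
})

test_that("lookup returns counts or an explicit absent marker", {
  tab <- buildReferenceTable(rep("CCO", 150), minCount = 100)
  eth <- extractShingles(parseMolecule("CCO"))$text
  expect_true(all(lookupShingle(tab, eth) == 150L))
  bz <- extractShingles(parseMolecule("c1ccccc1"))$text
  expect_true(all(is.na(lookupShingle(tab, bz))))
  empty <- buildReferenceTable(character(0), minCount = 100)
  expect_true(is.na(lookupShingle(empty, "CC")))
})

test_that("counts match the molecule-presence oracle on random corpora", {
  for (seed in c(3, 17, 28)) {
    corpus <- randomFixtureSmiles(80, seed = seed)
    tab <- buildReferenceTable(corpus, minCount = 1)
    oracle <- oraclePresenceCounts(corpus)
    expect_identical(sort(names(tab@entries)), sort(names(oracle)))
    expect_equal(tab@entries[names(oracle)], oracle[names(oracle)],
                 ignore_attr = TRUE)
  }
})

test_that("raising minCount only removes entries, never changes counts", {
  corpus <- randomFixtureSmiles(120, seed = 5)
  t1 <- buildReferenceTable(corpus, minCount = 1)
  for (mc in c(2, 5, 10, 25)) {
    tm <- buildReferenceTable(corpus, minCount = mc)
    expect_true(all(names(tm@entries) %in% names(t1@entries)))
    expect_equal(tm@entries, t1@entries[t1@entries >= mc], ignore_attr = FALSE)
  }
})

test_that("corpus order does not affect the table", {
  corpus <- randomFixtureSmiles(60, seed = 9)
  t1 <- buildReferenceTable(corpus, minCount = 2)
  t2 <- buildReferenceTable(rev(corpus), minCount = 2)
  expect_identical(t1@entries, t2@entries)
})

test_that("unparseable records are skipped and counted; all-failed warns", {
  tab <- suppressWarnings(
    buildReferenceTable(c("CCO", "C1CC", "CCO", "notsmiles"), minCount = 1))
  expect_equal(tab@nMolecules, 2L)
  expect_equal(tab@nParseFailures, 2L)
  expect_true(all(tab@entries == 2L))
  expect_error(buildReferenceTable(c("CCO", "C1CC"), minCount = 1,
                                   strict = TRUE),
               class = "clscore_parse_error")
  expect_warning(bad <- buildReferenceTable(c("C1CC", "xx"), minCount = 1),
                 "no corpus record parsed")
  expect_equal(length(bad), 0L)
})

test_that("deduplication collapses identical structures when requested", {
  corpus <- c(rep("CCO", 5), rep("OCC", 5))  # same molecule, two renderings
  expect_true(all(buildReferenceTable(corpus, minCount = 1)@entries == 10L))
  expect_true(all(buildReferenceTable(corpus, minCount = 1,
                                      dedupe = TRUE)@entries == 1L))
})

test_that("save/load round trip is lossless and byte-stable", {
  tab <- buildReferenceTable(randomFixtureSmiles(40, seed = 13), minCount = 2,
                             corpusName = "roundtrip")
  path <- withr::local_tempfile(fileext = ".tsv")
  saveShingleTable(tab, path)
  back <- loadShingleTable(path)
  expect_identical(back@entries, tab@entries)
  for (sl in c("corpusName", "nMolecules", "nParseFailures", "minCount",
               "minRadius", "maxRadius", "canonicalizationTag"))
    expect_identical(methods::slot(back, sl), methods::slot(tab, sl), info = sl)
  # keys are written in bytewise sorted order; a second save is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  saveShingleTable(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  # empty table round trip keeps metadata
  e <- buildReferenceTable(character(0), minCount = 7, corpusName = "none")
  saveShingleTable(e, path)
  eb <- loadShingleTable(path)
  expect_equal(length(eb), 0L)
  expect_equal(eb@minCount, 7L)
  expect_equal(eb@corpusName, "none")
})

test_that("malformed table files raise format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- buildReferenceTable(rep("CCO", 10), minCount = 1)
  saveShingleTable(tab, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("^#min_count", lines)], path)
  expect_error(loadShingleTable(path), "min_count")
  writeLines(c(lines, "brokenline"), path)
  expect_error(loadShingleTable(path), "format error")
  writeLines(sub("\t150$|\t10$", "\tNaN", lines), path)
  expect_error(loadShingleTable(path), "format error")
})
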