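test_that("property triplets count heavy atoms, stereocenters and heteroatoms", {
  expect_equal(computeTriplet(parseMolecule("CCO")),
               c(hac = 3L, stereo_class = 0L, hetero_class = 1L))
  expect_equal(computeTriplet(parseMolecule("c1ccccc1")),
               c(hac = 6L, stereo_class = 0L, hetero_class = 0L))
  # one potential (unassigned) tetrahedral centre
  expect_equal(computeTriplet(parseMolecule("CC(N)C(=O)O")),
               c(hac = 6L, stereo_class = 1L, hetero_class = 3L))
  # merge rules cap the classes: 6 stereocenters -> class 5, 9 heteroatoms -> 8
  m <- parseMolecule("C(F)(Cl)C(F)(Br)C(Cl)(Br)C(F)(I)C(Cl)(I)C(Br)(I)O")
  expect_equal(stereoCenterCount(m), 6L)
  expect_equal(heteroAtomCount(m), 13L)
  expect_equal(unname(computeTriplet(m)), c(19L, 5L, 8L))
  # thresholds are configurable
  expect_equal(unname(computeTriplet(m, stereoMerge = 10, heteroMerge = 20)),
               c(19L, 6L, 13L))
  # assigned-only mode counts only input-marked centres
  ala <- parseMolecule("C[C@H](N)C(=O)O")
  expect_equal(stereoCenterCount(ala, "assigned"), 1L)
  expect_equal(stereoCenterCount(parseMolecule("CC(N)C(=O)O"), "assigned"), 0L)
  # symmetric substituents disqualify a centre
  expect_equal(stereoCenterCount(parseMolecule("CC(C)O")), 0L)
  expect_equal(stereoCenterCount(parseMolecule("CC1CCC(O)CC1")), 0L)
})

test_that("census counts bins exactly and supports spill files", {
  cs <- censusRecords(c("CCO", "CCO", "c1ccccc1"))
  expect_equal(attr(cs, "total"), 3L)
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$count[cs$hac == 3L], 2L)
  expect_equal(cs$count[cs$hac == 6L], 1L)

  expect_equal(nrow(censusRecords(character(0))), 0L)
  one <- censusRecords(rep("CCN", 10))
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 10L)

  dir <- withr::local_tempdir()
  recs <- data.frame(smiles = c("CCO", "CCN", "CCO"),
                     id = c("a", "b", "c"),
                     text = c("CCO a", "CCN b", "CCO c"))
  cs2 <- censusRecords(recs, spillDir = dir)
  files <- list.files(dir)
  expect_length(files, nrow(cs2))
  spilled <- sort(unlist(lapply(file.path(dir, files), readLines)))
  expect_identical(spilled, sort(recs$text))
})

test_that("the even allocator follows the documented iteration", {
  census <- data.frame(hac = c(4L, 5L, 6L), stereo_class = 0L,
                       hetero_class = 0L, count = c(5L, 10L, 100L))
  # trace: pass 1 quota 10 exhausts A; pass 2 quota 12.5 exhausts B; final 15
  expect_equal(allocateUniform(census, 30)$quota, c(5L, 10L, 15L))
  # everything is taken when the target covers the total
  expect_equal(allocateUniform(census, 200)$quota, census$count)
  expect_equal(allocateUniform(census, 115)$quota, census$count)
  # single bin
  one <- census[3, ]
  expect_equal(allocateUniform(one, 10)$quota, 10L)
  expect_equal(allocateUniform(census, 0)$quota, rep(0L, 3))
  expect_error(allocateUniform(census, -1), "target")
})

test_that("allocator invariants hold over random censuses", {
  set.seed(99)
  for (rep in 1:200) {
    cs <- randomCensus(sample.int(30L, 1L))
    total <- sum(cs$count)
    target <- sample.int(2L * total, 1L) - 1L
    al <- allocateUniform(cs, target)
    expect_equal(sum(al$quota), min(target, total))
    expect_true(all(al$quota <= al$count))
    open <- al$quota < al$count
    if (any(open)) {
      expect_lte(diff(range(al$quota[open])), 1L)
      # exhaustion ordering: a fully-taken bin is never larger than an open
      # bin's quota, except by one when the +1 top-up exhausted it
      if (any(!open))
        expect_lte(max(al$count[!open]), min(al$quota[open]) + 1L)
    }
  }
})

test_that("sampling is deterministic under a seed and exact per quota", {
  lines <- sprintf("CCO r%03d", 1:100)
  al <- data.frame(hac = 3L, stereo_class = 0L, hetero_class = 1L,
                   count = 100L, quota = 15L)
  s1 <- drawSample(al, seed = 42L, records = lines)
  s2 <- drawSample(al, seed = 42L, records = lines)
  expect_identical(s1, s2)
  expect_length(s1, 15L)
  expect_true(all(s1 %in% lines))
  expect_false(anyDuplicated(s1) > 0L)
  s3 <- drawSample(al, seed = 43L, records = lines)
  expect_false(identical(s1, s3))

  # exhaustive bin returns everything; zero quota returns nothing
  al$quota <- 100L
  expect_identical(drawSample(al, 1L, records = lines), lines)
  al$quota <- 0L
  expect_length(drawSample(al, 1L, records = lines), 0L)

  # quota exceeding availability is a consistency error
  al$quota <- 101L
  expect_error(drawSample(al, 1L, records = lines), "mismatch")
})

test_that("spill-file sampling matches the in-memory path and bin order", {
  dir <- withr::local_tempdir()
  recs <- generateQuerySet(200, seed = 8)
  lines <- paste(recs$smiles, recs$id)
  cs <- censusRecords(data.frame(smiles = recs$smiles, id = recs$id,
                                 text = lines), spillDir = dir)
  al <- allocateUniform(cs, 50)
  a <- drawSample(al, seed = 7L, spillDir = dir)
  b <- drawSample(al, seed = 7L, records = lines)
  expect_identical(a, b)
  expect_length(a, 50L)
  # output follows bin-key order
  keyOf <- function(line) {
    sm <- strsplit(line, " ")[[1]][1]
    tr <- computeTriplet(parseMolecule(sm))
    sprintf("%05d_%02d_%02d", tr[1], tr[2], tr[3])
  }
  expect_false(is.unsorted(vapply(a, keyOf, character(1))))
})

test_that("the sampler state does not leak into the caller's RNG", {
  lines <- sprintf("CCN x%d", 1:50)
  al <- data.frame(hac = 3L, stereo_class = 0L, hetero_class = 1L,
                   count = 50L, quota = 5L)
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(drawSample(al, 99L, records = lines)); after <- runif(3)
  expect_identical(before, after)
})
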