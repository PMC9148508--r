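# Training-set parsing, writing, GC binning and the state inventory.

test_that("write/read round trip reproduces generated parameters", {
  m <- generateParams(42, symmetric = FALSE, geneStrength = 3,
                      binRange = c(48L, 52L))
  dir <- withr::local_tempdir()
  writeTrainingSet(m, dir)
  m2 <- readTrainingSet(dir, "complete")

  expect_identical(gcBinRange(m2), gcBinRange(m))
  expect_equal(exp(m2@transitions), exp(m@transitions), tolerance = 1e-9)
  for (k in names(m@bins)) {
    for (p in 1:6) {
      expect_equal(exp(m2@bins[[k]]$match[[p]]), exp(m@bins[[k]]$match[[p]]),
                   tolerance = 1e-9)
      expect_equal(exp(m2@bins[[k]]$rmatch[[p]]),
                   exp(m@bins[[k]]$rmatch[[p]]), tolerance = 1e-9)
    }
    for (tab in c("noncoding", "start", "stop", "rstart", "rstop"))
      expect_equal(exp(m2@bins[[k]][[tab]]), exp(m@bins[[k]][[tab]]),
                   tolerance = 1e-9)
  }
  expect_equal(m2@adjust, m@adjust, tolerance = 1e-9)
  expect_true(validObject(m2))
})

test_that("error-model conditions share emissions but differ in indel rates", {
  dir <- withr::local_tempdir()
  writeTrainingSet(generateParams(5, condition = "complete",
                                  insertRate = 1e-4, deleteRate = 1e-4,
                                  binRange = c(49L, 51L)), dir)
  writeTrainingSet(generateParams(5, condition = "454_10",
                                  insertRate = 5e-3, deleteRate = 5e-3,
                                  binRange = c(49L, 51L)), dir)
  a <- readTrainingSet(dir, "complete")
  b <- readTrainingSet(dir, "454_10")
  expect_identical(a@bins, b@bins)
  expect_lt(a@transitions[["MI"]], b@transitions[["MI"]])
  expect_lt(a@transitions[["MD"]], b@transitions[["MD"]])
  expect_equal(exp(b@transitions[["MI"]]), 5e-3, tolerance = 1e-6)
})

test_that("parsing is strict: missing files, malformed rows, bad distributions", {
  dir <- withr::local_tempdir()
  writeTrainingSet(generateParams(7, binRange = c(50L, 51L)), dir)

  broken <- withr::local_tempdir()
  file.copy(list.files(dir, full.names = TRUE), broken)
  unlink(file.path(broken, "noncoding"))
  expect_error(readTrainingSet(broken, "complete"),
               "training file not found.*noncoding")

  broken2 <- withr::local_tempdir()
  file.copy(list.files(dir, full.names = TRUE), broken2)
  lines <- readLines(file.path(broken2, "gene"))
  lines[3] <- "0.1 0.2 oops 0.3"
  writeLines(lines, file.path(broken2, "gene"))
  expect_error(readTrainingSet(broken2, "complete"), "gene, line 3")

  broken3 <- withr::local_tempdir()
  file.copy(list.files(dir, full.names = TRUE), broken3)
  lines <- readLines(file.path(broken3, "gene"))
  lines[2] <- "0.5 0.5 0.5 0.5"
  writeLines(lines, file.path(broken3, "gene"))
  expect_error(readTrainingSet(broken3, "complete"), "sums to")

  broken4 <- withr::local_tempdir()
  file.copy(list.files(dir, full.names = TRUE), broken4)
  lines <- readLines(file.path(broken4, "gene"))
  writeLines(c(lines[1:97], lines), file.path(broken4, "gene"))
  expect_error(readTrainingSet(broken4, "complete"), "duplicate GC bin")
})

test_that("embedded defaults equal the packaged text files and validate names", {
  m <- defaultModel("complete")
  m2 <- readTrainingSet(system.file("extdata", "training_synthetic",
                                    package = "fgsr"), "complete")
  expect_identical(m@bins, m2@bins)
  expect_identical(m@transitions, m2@transitions)
  expect_identical(m@adjust, m2@adjust)
  expect_error(defaultModel("no_such_condition"),
               "unknown condition.*complete")
  for (cn in defaultConditions())
    expect_s4_class(defaultModel(cn), "FgsModel")
})

test_that("loaded emission rows are normalised within 1e-6", {
  m <- defaultModel("complete")
  b <- binParams(m, 50)
  expect_equal(rowSums(exp(b$match[[4]])), rep(1, 16), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(exp(b$noncoding)), rep(1, 16), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(exp(b$start)), rep(1, m@window), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("gcBin rounds, clamps, excludes ambiguous bases and is monotone", {
  m <- defaultModel("complete")
  lo <- gcBinRange(m)[1]; hi <- gcBinRange(m)[2]
  expect_identical(gcBin("ATAT", m), lo)
  expect_identical(gcBin("GCGC", m), hi)
  expect_identical(gcBin("ATGC"), 50L)
  expect_identical(gcBin("GCNN", m), hi)     # ambiguous bases excluded
  expect_identical(gcBin("NNNN", m), 50L)    # no informative base
  expect_error(gcBin("", m), "empty")

  set.seed(1)
  fr <- sort(runif(25))
  bins <- vapply(fr, function(f) {
    n <- 200L
    g <- round(f * n)
    gcBin(paste(c(rep("G", g), rep("A", n - g)), collapse = ""), m)
  }, 0L)
  expect_true(all(diff(bins) >= 0))
  expect_identical(range(bins), c(lo, hi))
})

test_that("state inventory counts 49 states in 6 periodic groups", {
  inv <- stateInventory(defaultModel("complete"))
  expect_identical(stateCount(inv), 49L)
  expect_length(periodicGroups(inv), 6L)
  expect_identical(unname(lengths(periodicGroups(inv))), rep(6L, 6))
  counts <- table(inv@role)
  expect_identical(
    vapply(c("match", "insertion", "deletion", "boundary", "noncoding"),
           function(r) as.integer(counts[[r]]), 0L),
    c(match = 12L, insertion = 12L, deletion = 12L, boundary = 12L,
      noncoding = 1L))
  # periodic groups partition exactly the gene-region states
  expect_setequal(unlist(periodicGroups(inv)),
                  inv@states[inv@role %in% c("match", "insertion", "deletion")])
  expect_length(decodingRows(inv), 29L)
})
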