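# The synthetic generators and the brute-force oracle's own contracts.

test_that("parameter generation is reproducible and valid", {
  m1 <- generateParams(1, symmetric = TRUE)
  m2 <- generateParams(1, symmetric = TRUE)
  expect_identical(m1, m2)
  expect_true(validObject(m1))
  expect_true(validObject(generateParams(2, symmetric = FALSE)))
  expect_false(identical(generateParams(3), generateParams(4)))
})

test_that("vanishing gene strength collapses coding onto noncoding", {
  m <- generateParams(9, symmetric = TRUE, geneStrength = 1e-12)
  b <- binParams(m, 50)
  for (p in 1:6)
    expect_equal(exp(b$match[[p]]), exp(b$noncoding), tolerance = 1e-9)
})

test_that("symmetric mode builds exact reverse-complement transforms", {
  m <- generateParams(14, symmetric = TRUE)
  b <- binParams(m, 50)
  expect_equal(exp(b$rstart), fgsr:::.revcompPwm(exp(b$start)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(exp(b$rstop), fgsr:::.revcompPwm(exp(b$stop)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # complement-mirrored 3-periodic match tables
  for (p in 1:6) {
    cp <- fgsr:::.codonPos(p)
    fwd <- exp(b$match[[which(vapply(1:6, fgsr:::.codonPos, 0L) ==
                                (4L - cp))[1]]])[1, ]
    expect_equal(exp(b$rmatch[[p]])[1, ], unname(fwd[c(4, 3, 2, 1)]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("read simulation records truth exactly and reproducibly", {
  m <- generateParams(6, symmetric = TRUE, geneStrength = 8)
  g1 <- generateReads(m, n = 15, length = 200, seed = 77)
  g2 <- generateReads(m, n = 15, length = 200, seed = 77)
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  writeFasta(g1$seqs, f1); writeFasta(g2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))

  tr <- g1$truth
  expect_true(all(tr$start >= 1 & tr$end <= nchar(as.character(g1$seqs)) &
                    tr$start < tr$end))
  expect_true(all(vapply(tr$inserts, length, 0L) == 0L))
  expect_true(all(vapply(tr$deletes, length, 0L) == 0L))

  gi <- generateReads(m, n = 15, length = 200, insertRate = 0.05,
                      deleteRate = 0.05, seed = 78)
  expect_gt(sum(lengths(gi$truth$inserts)), 0L)
  expect_gt(sum(lengths(gi$truth$deletes)), 0L)
  # indel positions lie inside the recorded gene
  for (i in seq_len(nrow(gi$truth))) {
    idx <- c(gi$truth$inserts[[i]], gi$truth$deletes[[i]])
    if (length(idx))
      expect_true(all(idx > gi$truth$start[i] & idx < gi$truth$end[i]))
  }
})

test_that("generator does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generateParams(5))
  invisible(generateReads(generateParams(5), n = 2, length = 100, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("truth annotations serialise in the metadata layout", {
  m <- generateParams(6, symmetric = TRUE)
  g <- generateReads(m, n = 3, length = 120, seed = 2)
  f <- tempfile()
  on.exit(unlink(f))
  writeTruth(g$truth, f)
  lines <- readLines(f)
  expect_identical(lines[1], "# seed=2")
  expect_identical(sum(startsWith(lines, ">")), 3L)
  gene <- strsplit(lines[3], "\t")[[1]]
  expect_length(gene, 7L)
  expect_true(startsWith(gene[6], "I:"))
  expect_true(startsWith(gene[7], "D:"))
})

test_that("brute force refuses long input and optimises single positions", {
  m <- generateParams(8)
  expect_error(bruteForceDecode(m, randomSeq(13)), "12 nt")
  # a single position: best row by direct comparison of prior + step score
  s <- "G"
  S <- fgsr:::.stepMatrix(m, fgsr:::.encodeSeq(s), gcBin(s, m))
  direct <- max(fgsr:::.logPrior() + S[fgsr:::.rowConsumes() == 1L, 1])
  expect_equal(pathScore(bruteForceDecode(m, s)), direct, tolerance = 1e-12)
})
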