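# Viterbi decoding against the exhaustive enumeration oracle, boundary
# scoring, and path-scoring semantics.

test_that("decoding matches exhaustive enumeration on short sequences", {
  models <- list(generateParams(11), generateParams(12, symmetric = TRUE),
                 uniformModel())
  set.seed(101)
  for (m in models) {
    for (k in 1:20) {
      s <- randomSeq(sample(c(1:8, 9), 1),
                     alphabet = c("A", "C", "G", "T", "N"))
      bf <- bruteForceDecode(m, s)
      vt <- viterbiDecode(m, s)
      expect_equal(pathScore(vt), pathScore(bf), tolerance = 1e-9)
      # any enumerated legal path scores no better than the optimum
      expect_lte(pathScore(bf), pathScore(vt) + 1e-9)
    }
  }
})

test_that("ties resolve to the same path as the enumeration oracle", {
  m <- uniformModel(tied = TRUE)
  set.seed(7)
  for (k in 1:12) {
    s <- randomSeq(sample(1:7, 1))
    expect_identical(pathStates(viterbiDecode(m, s)),
                     pathStates(bruteForceDecode(m, s)))
  }
})

test_that("scorePath reproduces the decoder's accumulation and rejects illegal paths", {
  m <- generateParams(13)
  set.seed(5)
  s <- randomSeq(60)
  vt <- viterbiDecode(m, s)
  expect_equal(scorePath(m, s, pathStates(vt)), pathScore(vt),
               tolerance = 1e-9)

  bad <- rep("R", 60); bad[10] <- "M3+"   # R -> M3+ is not an arc
  expect_error(scorePath(m, s, bad), "illegal transition R -> M3\\+.*10")
  badComp <- rep("R", 60); badComp[20:21] <- "S+"  # composite must span 3
  expect_error(scorePath(m, s, badComp), "S\\+.*3 positions")
  expect_error(scorePath(m, s, rep("R", 10)), "one label per")
})

test_that("a noncoding-dominant model decodes plain sequence as noncoding", {
  m <- noncodingFavoredModel()
  p <- viterbiDecode(m, "ACGTACGT")
  expect_identical(pathStates(p), rep("R", 8L))
})

test_that("planted strong gene decodes as start, cycling matches, stop", {
  m <- patternModel()
  rd <- patternRead(k = 6L)
  st <- pathStates(viterbiDecode(m, rd$seq))
  gs <- rd$geneStart; ge <- rd$geneEnd
  expect_identical(st[gs:(gs + 2)], rep("S+", 3))
  expect_identical(st[(ge - 2):ge], rep("E+", 3))
  interior <- st[(gs + 3):(ge - 3)]
  expect_identical(interior,
                   paste0("M", rep(1:6, length.out = length(interior)), "+"))
  expect_identical(st[1:(gs - 1)], rep("R", gs - 1))
})

test_that("boundary scores combine PWM and adjustment as documented", {
  mu <- uniformModel()
  W <- mu@window
  s <- randomSeq(30)
  expect_equal(boundaryScore(mu, s, 10, "start"), W * log(0.25),
               tolerance = 1e-12)
  # left-truncated window at the sequence edge stays finite
  expect_true(is.finite(boundaryScore(mu, s, 1, "start")))
  expect_lt(abs(boundaryScore(mu, s, 1, "start")),
            abs(W * log(0.25)))

  mp <- patternModel()
  rd <- patternRead()
  inRegister <- boundaryScore(mp, rd$seq, rd$geneStart, "start")
  shifted <- boundaryScore(mp, rd$seq, rd$geneStart + 1, "start")
  expect_gt(inRegister, shifted)
  expect_error(boundaryScore(mp, rd$seq, 5, "middle"), "unknown boundary kind")
})

test_that("ambiguous bases are handled and degenerate inputs behave", {
  m <- defaultModel("complete")
  expect_error(viterbiDecode(m, ""), "empty")
  pN <- viterbiDecode(m, "NNNNNNNNNN")
  expect_identical(pathStates(pN), rep("R", 10L))
  expect_true(is.finite(pathScore(pN)))
  s <- "ACGTNNACGTACGNTACGT"
  p <- viterbiDecode(m, s)
  expect_true(is.finite(pathScore(p)))
  expect_equal(scorePath(m, s, pathStates(p)), pathScore(p), tolerance = 1e-9)
})

test_that("decoding is deterministic and respects period discipline", {
  m <- generateParams(31, symmetric = TRUE, geneStrength = 8,
                      insertRate = 0.01, deleteRate = 0.01)
  g <- generateReads(m, n = 6, length = 200, insertRate = 0.02,
                     deleteRate = 0.02, seed = 4)
  for (i in seq_along(g$seqs)) {
    s <- as.character(g$seqs[[i]])
    p1 <- viterbiDecode(m, s)
    p2 <- viterbiDecode(m, s)
    expect_identical(pathStates(p1), pathStates(p2))
    expect_identical(pathScore(p1), pathScore(p2))
    expect_true(checkPeriodDiscipline(pathStates(p1)))
  }
})

test_that("DP work grows linearly with sequence length", {
  m <- defaultModel("complete")
  set.seed(9)
  n1 <- viterbiDecode(m, randomSeq(1500))@opCount
  n2 <- viterbiDecode(m, randomSeq(3000))@opCount
  expect_gte(n2 / n1, 1.8)
  expect_lte(n2 / n1, 2.2)
})
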