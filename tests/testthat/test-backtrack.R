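# Gene extraction, the unified annotated-DNA representation, renderings,
# translation and reverse complement.

test_that("reverse complement follows the documented rules", {
  expect_identical(revComp("ATGC"), "GCAT")
  expect_identical(revComp("AnT"), "AnT")
  set.seed(2)
  for (k in 1:10) {
    s <- randomSeq(sample(1:40, 1), c("A", "C", "G", "T", "N", "a", "t"))
    expect_identical(revComp(revComp(s)), s)
  }
  expect_error(revComp("ACGU"), "outside")
})

test_that("translation uses table 11 with the start, N and stop rules", {
  expect_identical(translateGene("ATGAAA", "+"), "MK")
  expect_identical(translateGene("TTTCAT", "-"), "MK")
  expect_identical(translateGene("ATGAANAAA", "+"), "MXK")
  expect_identical(translateGene("GTGAAA", "+", hasStart = TRUE), "MK")
  expect_identical(translateGene("GTGAAA", "+", hasStart = FALSE), "VK")
  expect_identical(translateGene("TTGAAA", "+"), "MK")
  expect_identical(translateGene("ATGAAATAA", "+"), "MK")   # terminal stop
  expect_identical(translateGene("ATGAAAA", "+"), "MK")     # trailing base
  expect_identical(translateGene("AT", "+"), "")
})

test_that("clean planted gene yields exact coordinates and renderings", {
  m <- patternModel()
  rd <- patternRead(k = 6L)
  p <- viterbiDecode(m, rd$seq)
  genes <- extractGenes(m, p, rd$seq, "r1")
  expect_length(genes, 1L)
  expect_identical(GenomicRanges::start(genes), rd$geneStart)
  expect_identical(GenomicRanges::end(genes), rd$geneEnd)
  expect_identical(as.character(GenomicRanges::strand(genes)), "+")
  mc <- S4Vectors::mcols(genes)
  expect_identical(mc$frame, ((rd$geneStart - 1L) %% 3L) + 1L)
  expect_length(mc$inserts[[1]], 0L)
  expect_length(mc$deletes[[1]], 0L)
  expect_true(mc$hasStart && mc$hasStop)
  # no indels: both renderings equal the spanned sequence
  expect_identical(renderDna(genes, formatted = TRUE),
                   renderDna(genes, formatted = FALSE))
  expect_identical(renderDna(genes),
                   substr(rd$seq, rd$geneStart, rd$geneEnd))
  expect_identical(nchar(renderDna(genes)) %% 3L, 0L)
})

test_that("an all-noncoding path yields no genes", {
  m <- noncodingFavoredModel()
  s <- "ACGTACGTACGTACGT"
  genes <- extractGenes(m, viterbiDecode(m, s), s, "r1")
  expect_length(genes, 0L)
})

test_that("a planted insertion is recovered at exactly its position", {
  m <- patternModel()
  rd <- patternRead(k = 8L)
  insPos <- rd$geneStart + 10L    # inside the interior
  # insert a base that breaks the deterministic pattern at that point
  s <- insertAt(rd$seq, insPos, "G")
  genes <- extractGenes(m, viterbiDecode(m, s), s, "r1")
  expect_length(genes, 1L)
  mc <- S4Vectors::mcols(genes)
  expect_identical(as.integer(mc$inserts[[1]]), insPos)
  expect_length(mc$deletes[[1]], 0L)
  fmt <- renderDna(genes, formatted = TRUE)
  unf <- renderDna(genes, formatted = FALSE)
  expect_identical(nchar(fmt), nchar(unf) + 1L)
  expect_identical(substr(fmt, insPos - rd$geneStart + 1L,
                          insPos - rd$geneStart + 1L), "g")
  # stripping insertion marks reproduces the unformatted rendering
  expect_identical(toupper(gsub("-", "N", gsub("[a-z]", "", fmt))), unf)
})

test_that("a planted deletion is recovered and the placeholder filled", {
  m <- patternModel()
  rd <- patternRead(k = 8L)
  delPos <- rd$geneStart + 11L
  s <- deleteAt(rd$seq, delPos)
  genes <- extractGenes(m, viterbiDecode(m, s), s, "r1")
  expect_length(genes, 1L)
  mc <- S4Vectors::mcols(genes)
  expect_identical(as.integer(mc$deletes[[1]]), delPos)
  fmt <- renderDna(genes, formatted = TRUE)
  unf <- renderDna(genes, formatted = FALSE)
  expect_identical(nchar(unf), nchar(fmt))   # "-" replaced by "N"
  expect_true(grepl("-", fmt, fixed = TRUE))
  expect_true(grepl("N", unf, fixed = TRUE))
  # frame correction: length is a codon multiple again
  expect_identical(nchar(unf) %% 3L, 0L)
})

test_that("coordinate arithmetic links renderings to indel counts", {
  m <- generateParams(55, symmetric = TRUE, geneStrength = 12,
                      insertRate = 0.01, deleteRate = 0.01)
  g <- generateReads(m, n = 12, length = 240, insertRate = 0.02,
                     deleteRate = 0.02, seed = 8)
  seen <- 0L
  for (i in seq_along(g$seqs)) {
    s <- as.character(g$seqs[[i]])
    genes <- extractGenes(m, viterbiDecode(m, s), s, g$truth$read_id[i])
    if (length(genes) == 0) next
    mc <- S4Vectors::mcols(genes)
    span <- GenomicRanges::width(genes)
    expect_identical(nchar(renderDna(genes, formatted = FALSE)),
                     span - lengths(mc$inserts) + lengths(mc$deletes))
    expect_identical(nchar(renderDna(genes, formatted = TRUE)),
                     span + lengths(mc$deletes))
    # sorted, non-overlapping
    if (length(genes) > 1) {
      expect_true(all(diff(GenomicRanges::start(genes)) > 0))
      expect_true(all(GenomicRanges::start(genes)[-1] >
                        GenomicRanges::end(genes)[-length(genes)]))
    }
    seen <- seen + length(genes)
  }
  expect_gt(seen, 5L)
})

test_that("emitted proteins match an independent per-codon translation", {
  m <- generateParams(56, symmetric = TRUE, geneStrength = 12,
                      insertRate = 0.01, deleteRate = 0.01)
  g <- generateReads(m, n = 10, length = 240, insertRate = 0.03,
                     deleteRate = 0.03, seed = 20)
  checked <- 0L
  for (i in seq_along(g$seqs)) {
    s <- as.character(g$seqs[[i]])
    genes <- extractGenes(m, viterbiDecode(m, s), s, g$truth$read_id[i])
    if (length(genes) == 0) next
    mc <- S4Vectors::mcols(genes)
    dna <- renderDna(genes, formatted = FALSE)
    for (k in seq_along(genes)) {
      strand <- as.character(GenomicRanges::strand(genes))[k]
      expect_identical(
        translateGene(dna[k], strand, hasStart = mc$hasStart[k]),
        indepTranslate(dna[k], strand, hasStart = mc$hasStart[k]))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)
})
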