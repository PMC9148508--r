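# Hand-constructed fixture models with known, analysable behaviour.

.uniRow <- rep(0.25, 4)

.peak <- function(base, p = 0.97) {
  v <- rep((1 - p) / 3, 4)
  v[match(base, c("A", "C", "G", "T"))] <- p
  v
}

.stdTrans <- c(NN = 0.99, NSF = 0.005, NER = 0.005, MM = 0.998, MI = 0.001,
               MD = 0.001, II = 0.2, IM = 0.8, GE = 0.01)

.mkBin <- function(match, rmatch, noncoding, start, stop, rstart, rstop) {
  list(match = match, rmatch = rmatch, noncoding = noncoding,
       start = start, stop = stop, rstart = rstart, rstop = rstop)
}

.uniformPwm <- function(W = 5L) matrix(0.25, W, 4L)

.buildModel <- function(bin, trans = .stdTrans, W = 5L) {
  bins <- list(`50` = bin)
  adjust <- matrix(1 / W, 4L, W,
                   dimnames = list(c("start", "stop", "rev_start", "rev_stop"),
                                   NULL))
  fgsr:::.makeModel("complete", trans, bins, adjust)
}

# every emission and PWM uniform; optionally all transition branches tied,
# which floods the DP with exact score ties (tie-break stress fixture)
uniformModel <- function(tied = FALSE) {
  rep16 <- fgsr:::.repRows(.uniRow)
  bin <- .mkBin(rep(list(rep16), 6), rep(list(rep16), 6), rep16,
                .uniformPwm(), .uniformPwm(), .uniformPwm(), .uniformPwm())
  trans <- if (tied)
    c(NN = 1 / 3, NSF = 1 / 3, NER = 1 / 3, MM = 1 / 3, MI = 1 / 3,
      MD = 1 / 3, II = 0.5, IM = 0.5, GE = 0.5)
  else .stdTrans
  .buildModel(bin, trans)
}

# coding states all but refuse anything except 'A'; noncoding uniform --
# any sequence with non-A bases decodes entirely noncoding
noncodingFavoredModel <- function() {
  aRow <- fgsr:::.repRows(.peak("A"))
  bin <- .mkBin(rep(list(aRow), 6), rep(list(aRow), 6),
                fgsr:::.repRows(.uniRow),
                .uniformPwm(), .uniformPwm(), .uniformPwm(), .uniformPwm())
  .buildModel(bin)
}

# near-deterministic six-periodic codon pattern with peaked ATG/TAA
# boundary PWMs; planted reads have a unique optimal alignment, so exact
# indel positions are recoverable
.PATTERN <- c("A", "T", "G", "C", "T", "C")

patternModel <- function(insertRate = 0.01, deleteRate = 0.01) {
  match <- lapply(.PATTERN, function(b) fgsr:::.repRows(.peak(b)))
  W <- 5L
  half <- 2L
  mkPwm <- function(codon) {
    m <- .uniformPwm(W)
    for (k in 1:3) m[half + k - 1L, ] <- .peak(codon[k])
    m
  }
  start <- mkPwm(c("A", "T", "G"))
  stopP <- mkPwm(c("T", "A", "A"))
  bin <- .mkBin(match, match, fgsr:::.repRows(.uniRow),
                start, stopP, fgsr:::.revcompPwm(start),
                fgsr:::.revcompPwm(stopP))
  trans <- .stdTrans
  trans["MI"] <- insertRate; trans["MD"] <- deleteRate
  trans["MM"] <- 1 - insertRate - deleteRate
  .buildModel(bin, trans)
}

# error-free read for patternModel: flank + ATG + k pattern codon-pairs + TAA
patternRead <- function(k = 6L, flank = 10L) {
  interior <- paste(rep(.PATTERN, length.out = 3L * k), collapse = "")
  fl <- paste(rep(c("A", "C"), length.out = flank), collapse = "")
  list(seq = paste0(fl, "ATG", interior, "TAA", fl),
       geneStart = flank + 1L,
       geneEnd = flank + 6L + 3L * k)
}

insertAt <- function(seq, pos, base) {
  paste0(substr(seq, 1, pos - 1), base, substr(seq, pos, nchar(seq)))
}

deleteAt <- function(seq, pos) {
  paste0(substr(seq, 1, pos - 1), substr(seq, pos + 1, nchar(seq)))
}

# period-discipline checker: along every decoded path, consecutive match
# states advance the period by 1 mod 6, insertions hold it, and each
# deletion skip advances it by one extra
checkPeriodDiscipline <- function(states) {
  periodOf <- fgsr:::.rowPeriod()[match(states, fgsr:::.ROW_LABELS)]
  role <- substr(states, 1, 1)
  ok <- TRUE
  for (i in seq_along(states)[-1]) {
    if (role[i] == "M" && role[i - 1] == "M") {
      jump <- (periodOf[i] - periodOf[i - 1]) %% 6L
      if (!jump %in% c(1L, 2L)) ok <- FALSE
    }
    if (role[i] == "I" && role[i - 1] %in% c("M", "I")) {
      if (periodOf[i] != periodOf[i - 1] &&
          !(role[i - 1] == "M" && periodOf[i] == periodOf[i - 1]))
        ok <- FALSE
    }
    if (role[i] == "M" && role[i - 1] == "I") {
      if ((periodOf[i] - periodOf[i - 1]) %% 6L != 1L) ok <- FALSE
    }
  }
  ok
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent codon-by-codon translation oracle (table 11, N -> X,
# terminal stop dropped, alternative initial start -> M)
indepTranslate <- function(dna, strand, hasStart = TRUE) {
  if (strand == "-") dna <- revComp(dna)
  gc <- Biostrings::getGeneticCode("11")
  n <- nchar(dna) %/% 3L
  aa <- character(n)
  for (j in seq_len(n)) {
    cd <- substr(dna, 3L * j - 2L, 3L * j)
    aa[j] <- if (grepl("N", cd, fixed = TRUE)) "X" else unname(gc[cd])
  }
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  if (hasStart && length(aa) &&
      substr(dna, 1L, 3L) %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}
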