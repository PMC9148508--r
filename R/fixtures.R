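# Synthetic training parameters and reads with recorded ground truth, plus
# an exhaustive brute-force decoder used as the Viterbi oracle.
#
# Randomness: every generator takes an explicit seed and runs R's
# Mersenne-Twister with inversion normals and rejection sampling (a named,
# portable, versioned algorithm), restoring the caller's RNG state
# afterwards, so fixtures are byte-stable across platforms and sessions.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.dirichletRow <- function(shape) {
  g <- rgamma(4L, shape)
  # guard against a degenerate all-tiny draw
  if (sum(g) < 1e-12) g <- g + 1e-12
  g / sum(g)
}

.peakRow <- function(base, peak) {
  p <- rep((1 - peak) / 3, 4L)
  p[match(base, .BASES)] <- peak
  p
}

# complement-mirror of an emission row: value at base b becomes the value
# at comp(b) (columns A C G T -> T G C A)
.compRow <- function(row) row[c(4L, 3L, 2L, 1L)]

# reverse-complement transform of a positional weight matrix: offset j
# becomes W+1-j and each row is complement-mirrored
.revcompPwm <- function(m) m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L),
                             drop = FALSE]

.repRows <- function(row, n = 16L) matrix(rep(row, each = n), nrow = n)

# Assemble an FgsModel from raw (pre-log) tables. Used by the generator and
# by tests that need hand-constructed dominance models.
.makeModel <- function(condition, transRaw, bins, adjust) {
  W <- nrow(bins[[1]]$start)
  posRows <- as.character(seq_len(W))
  logBins <- lapply(bins, function(b) {
    list(match = lapply(b$match, .logMat),
         rmatch = lapply(b$rmatch, .logMat),
         noncoding = .logMat(b$noncoding),
         start = .logMat(b$start, posRows),
         stop = .logMat(b$stop, posRows),
         rstart = .logMat(b$rstart, posRows),
         rstop = .logMat(b$rstop, posRows))
  })
  keys <- as.integer(names(bins))
  new("FgsModel", condition = condition,
      transitions = .safeLog(transRaw[.TRANS_KEYS]), bins = logBins,
      binRange = range(keys), window = as.integer(W), adjust = adjust)
}

#' Generate a synthetic model parameter set
#'
#' Builds a valid, normalised [FgsModel-class] from a seed. With
#' `symmetric = TRUE` the reverse-strand tables are the exact
#' reverse-complement transform of the forward tables and all emission rows
#' are context-free and 3-periodic, which makes decoding strictly mirror
#' under reverse complementation (used by the strand-symmetry tests). With
#' `symmetric = FALSE` every emission row is an independent draw with full
#' dinucleotide-context dependence.
#'
#' `geneStrength` controls how sharply the codon emission tables deviate
#' from the noncoding background (mixing weight
#' `w = geneStrength / (1 + geneStrength)`); as `geneStrength` approaches 0
#' the gene and noncoding emissions coincide and the boundary PWMs flatten
#' to uniform. The start PWM peaks on ATG and the stop PWM on TAA at the
#' window centre with peak probability `0.25 + 0.72 w`; reverse-strand PWMs
#' are always the reverse-complement transform (a reverse gene really is
#' the reverse complement of a forward one). All GC bins in `binRange`
#' share one parameter set: per-bin variation adds nothing to the
#' properties the fixtures exercise.
#'
#' @param seed integer seed.
#' @param symmetric build strand-symmetric tables (see above).
#' @param geneStrength positive real; codon-bias sharpness.
#' @param condition condition name stored in the model.
#' @param insertRate,deleteRate per-base indel probabilities (`MI`, `MD`).
#' @param binRange integer GC bin range to populate.
#' @param window odd boundary-window length.
#' @param startProb noncoding-to-gene entry probability per strand.
#' @param geneExit gene exit branch weight `GE` at codon-boundary periods
#'   (mean gene length is about `3 / geneExit` bases).
#' @param insertExtend insertion extension probability `II`.
#' @return an [FgsModel-class].
#' @examples
#' m <- generateParams(1, symmetric = TRUE)
#' validObject(m)
#' @export
generateParams <- function(seed, symmetric = FALSE, geneStrength = 4,
                           condition = "complete",
                           insertRate = 1e-4, deleteRate = 1e-4,
                           binRange = c(45L, 55L), window = 5L,
                           startProb = 0.005, geneExit = 0.01,
                           insertExtend = 0.2) {
  stopifnot(window %% 2L == 1L, window >= 3L, geneStrength >= 0,
            insertRate >= 0, deleteRate >= 0, insertRate + deleteRate < 1)
  w <- geneStrength / (1 + geneStrength)
  peak <- 0.25 + 0.72 * w
  half <- (window - 1L) %/% 2L
  .withSeed(seed, {
    if (symmetric) {
      # complement-symmetric noncoding composition with realistic, moderate
      # AT/GC skew (extreme skews breed spurious stop-codon trigrams)
      u <- rgamma(2L, 12)
      ncRow <- c(u[1], u[2], u[2], u[1]) / (2 * sum(u))
      # strong codon bias means the three codon positions have *distinct*
      # dominant nucleotides (otherwise the table is aperiodic no matter
      # how sharp each row is), and coding statistics deplete in-frame
      # stop codons -- imposed here by keeping T off codon position 1.
      doms <- integer(3)
      doms[1] <- sample(1:3, 1L)                      # A, C or G; never T
      doms[2] <- sample(setdiff(1:4, doms[1]), 1L)
      doms[3] <- sample(setdiff(1:4, doms[1:2]), 1L)
      sharp <- lapply(1:3, function(cp) {
        peakMass <- runif(1L, 0.85, 0.97)
        rest <- rgamma(3L, 1)
        row <- numeric(4L)
        row[doms[cp]] <- peakMass
        row[sample(setdiff(1:4, doms[cp]))] <- (1 - peakMass) * rest / sum(rest)
        row
      })
      sharp[[1]][4L] <- min(sharp[[1]][4L], 0.02)
      sharp[[1]] <- sharp[[1]] / sum(sharp[[1]])
      fRow <- lapply(1:3, function(cp) (1 - w) * ncRow + w * sharp[[cp]])
      match <- lapply(1:6, function(p) .repRows(fRow[[.codonPos(p)]]))
      rmatch <- lapply(1:6, function(p)
        .repRows(.compRow(fRow[[4L - .codonPos(p)]])))
      noncoding <- .repRows(ncRow)
    } else {
      noncoding <- t(vapply(1:16, function(i) .dirichletRow(1), numeric(4)))
      mk <- function() lapply(1:6, function(p) {
        sharp <- t(vapply(1:16, function(i) .dirichletRow(0.35), numeric(4)))
        (1 - w) * noncoding + w * sharp
      })
      match <- mk(); rmatch <- mk()
    }
    flankRow <- function() .dirichletRow(60)   # near-uniform flanks
    mkPwm <- function(codon) {
      m <- t(vapply(seq_len(window), function(j) flankRow(), numeric(4)))
      for (k in 1:3)   # codon occupies offsets half..half+2 (centre half+1)
        m[half + k - 1L, ] <- .peakRow(codon[k], peak)
      m
    }
    startPwm <- mkPwm(c("A", "T", "G"))
    stopPwm <- mkPwm(c("T", "A", "A"))
    bin <- list(match = match, rmatch = rmatch, noncoding = noncoding,
                start = startPwm, stop = stopPwm,
                rstart = .revcompPwm(startPwm), rstop = .revcompPwm(stopPwm))
    bins <- rep(list(bin), binRange[2] - binRange[1] + 1L)
    names(bins) <- as.character(seq(binRange[1], binRange[2]))
    adjust <- matrix(1 / window, 4L, window,
                     dimnames = list(.BOUNDARY_KINDS, NULL))
    trans <- c(NN = 1 - 2 * startProb, NSF = startProb, NER = startProb,
               MM = 1 - insertRate - deleteRate, MI = insertRate,
               MD = deleteRate, II = insertExtend, IM = 1 - insertExtend,
               GE = geneExit)
    .makeModel(condition, trans, bins, adjust)
  })
}

.codonPos <- function(p) ((p - 1L) %% 3L) + 1L

.sampleBase <- function(tab, prev2) {
  ctx <- if (length(prev2) == 2L && !anyNA(match(prev2, .BASES)))
    (match(prev2[1], .BASES) - 1L) * 4L + match(prev2[2], .BASES)
  else sample.int(16L, 1L)
  sample(.BASES, 1L, prob = exp(tab[ctx, ]))
}

#' Simulate reads with planted genes and recorded ground truth
#'
#' Each read is drawn from the model's own generative process: noncoding
#' flank bases from the noncoding emission chain, then (with probability
#' `geneProb`) one planted gene — a start codon sampled from the start PWM
#' centre, interior codons cycling through the six periodic match tables,
#' and a stop codon — and a trailing noncoding flank. Reverse-strand genes
#' are planted as the reverse complement of a forward sample. Per-base
#' insertion/deletion errors at the stated rates are applied inside the
#' gene interior, respecting the model topology (the first and last
#' interior bases are never deleted, adjacent deletions and a deletion
#' immediately after an insertion never occur, and no insertion follows the
#' final interior base). Ground truth (coordinates, strand, frame, exact
#' indel positions in final-read coordinates, using the same position
#' conventions as [extractGenes()]) is recorded exactly.
#'
#' @param model an [FgsModel-class] (typically from [generateParams()]).
#' @param n number of reads.
#' @param length nominal error-free read length in bases (indels shift the
#'   final length).
#' @param insertRate,deleteRate per-base indel probabilities in `[0, 0.2]`.
#' @param seed integer seed.
#' @param strand `"both"` or `"forward"`.
#' @param geneProb probability that a read carries a planted gene.
#' @return a list with `seqs` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (a data.frame with columns `read_id`, `gene`, `start`, `end`,
#'   `strand`, `frame` and list columns `inserts`, `deletes`; attribute
#'   `seed`).
#' @export
generateReads <- function(model, n, length = 300L, insertRate = 0,
                          deleteRate = 0, seed = 1L,
                          strand = c("both", "forward"), geneProb = 1) {
  strand <- match.arg(strand)
  stopifnot(insertRate >= 0, insertRate <= 0.2,
            deleteRate >= 0, deleteRate <= 0.2, length >= 60L)
  bp <- binParams(model, mean(model@binRange))
  half <- (model@window - 1L) %/% 2L
  .withSeed(seed, {
    seqs <- character(n)
    truth <- vector("list", n)
    for (ri in seq_len(n)) {
      id <- sprintf("read_%05d", ri)
      hasGene <- runif(1) < geneProb
      if (!hasGene) {
        chars <- character(length)
        for (i in seq_len(length))
          chars[i] <- .sampleBase(bp$noncoding,
                                  if (i >= 3) chars[(i - 2):(i - 1)] else NULL)
        seqs[ri] <- paste(chars, collapse = "")
        truth[[ri]] <- data.frame(read_id = id, gene = FALSE,
                                  start = NA_integer_, end = NA_integer_,
                                  strand = NA_character_, frame = NA_integer_)
        truth[[ri]]$inserts <- list(integer(0))
        truth[[ri]]$deletes <- list(integer(0))
        next
      }
      kMax <- (length - 26L) %/% 3L
      k <- sample(10:max(10L, kMax), 1L)
      geneLen <- 6L + 3L * k
      flank <- length - geneLen
      left <- sample(seq(5L, flank - 5L), 1L)
      right <- flank - left
      gStrand <- if (strand == "both") sample(c("+", "-"), 1L) else "+"

      # canonical boundary codons: starts and stops are discrete signals,
      # not draws from the (smoothed) PWM
      gene <- c("A", "T", "G")
      for (q in seq_len(3L * k)) {
        p <- .wrap6(q)
        gene <- c(gene, .sampleBase(bp$match[[p]], tail(gene, 2L)))
      }
      gene <- c(gene, c("T", "A", "A"))
      # interior model positions eligible for errors, in gene-local coords
      interior <- 4L:(3L + 3L * k)

      if (gStrand == "-")
        gene <- strsplit(revComp(paste(gene, collapse = "")), "")[[1]]

      ncChars <- function(m) {
        out <- character(m)
        for (i in seq_len(m))
          out[i] <- .sampleBase(bp$noncoding,
                                if (i >= 3) out[(i - 2):(i - 1)] else NULL)
        out
      }
      pre <- ncChars(left); post <- ncChars(right)

      # apply indels inside the gene interior, tracking final coordinates
      out <- pre
      ins <- integer(0); del <- integer(0)
      forcedEmit <- FALSE
      gi <- seq_along(gene)
      lastInterior <- if (gStrand == "+") max(interior) else
        length(gene) - min(interior) + 1L
      firstInterior <- if (gStrand == "+") min(interior) else
        length(gene) - max(interior) + 1L
      pendingDelete <- FALSE
      for (q in gi) {
        inInterior <- q >= firstInterior && q <= lastInterior
        canDelete <- inInterior && q > firstInterior && q < lastInterior &&
          !forcedEmit
        if (canDelete && runif(1) < deleteRate) {
          pendingDelete <- TRUE
          forcedEmit <- TRUE      # no adjacent deletion
          next
        }
        forcedEmit <- FALSE
        out <- c(out, gene[q])
        if (pendingDelete) {
          del <- c(del, length(out))
          pendingDelete <- FALSE
        }
        if (inInterior && q < lastInterior && runif(1) < insertRate) {
          out <- c(out, sample(.BASES, 1L))
          ins <- c(ins, length(out))
          forcedEmit <- TRUE      # no deletion right after an insertion
        }
      }
      gStart <- left + 1L
      gEnd <- length(out)
      out <- c(out, post)
      seqs[ri] <- paste(out, collapse = "")
      nFinal <- length(out)
      frame <- if (gStrand == "+") ((gStart - 1L) %% 3L) + 1L
               else ((nFinal - gEnd) %% 3L) + 1L
      truth[[ri]] <- data.frame(read_id = id, gene = TRUE, start = gStart,
                                end = gEnd, strand = gStrand, frame = frame)
      truth[[ri]]$inserts <- list(ins)
      truth[[ri]]$deletes <- list(del)
    }
    names(seqs) <- sprintf("read_%05d", seq_len(n))
    truthDf <- do.call(rbind, truth)
    attr(truthDf, "seed") <- seed
    list(seqs = Biostrings::DNAStringSet(seqs), truth = truthDf)
  })
}

#' Write ground-truth annotations as tab-separated text
#'
#' Mirrors the metadata sink layout (one `>read_id` line per read, then one
#' tab-separated line per gene) so simulated truth and pipeline output can
#' be diffed directly; the score column is `NA` since truth has no score.
#'
#' @param truth the `truth` data.frame from [generateReads()].
#' @param path output file.
#' @export
writeTruth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", attr(truth, "seed")), con)
  for (i in seq_len(nrow(truth))) {
    writeLines(paste0(">", truth$read_id[i]), con)
    if (isTRUE(truth$gene[i]))
      writeLines(sprintf("%d\t%d\t%s\t%d\tNA\tI:%s\tD:%s",
                         truth$start[i], truth$end[i], truth$strand[i],
                         truth$frame[i],
                         paste(truth$inserts[[i]], collapse = ","),
                         paste(truth$deletes[[i]], collapse = ",")), con)
  }
  invisible(path)
}

#' Exhaustive brute-force decoder (Viterbi oracle)
#'
#' Enumerates every legal state path for a short sequence, scores each with
#' the same initial/transition/emission terms as [scorePath()], and returns
#' the maximum. Ties resolve exactly as in [viterbiDecode()]: among
#' equal-scoring paths the one whose row indices are smallest when compared
#' from the last position backwards wins (which is what per-cell
#' lowest-predecessor tie-breaking induces). Enumeration is exponential, so
#' sequences longer than 12 nt are refused.
#'
#' @param model an [FgsModel-class].
#' @param seq nucleotide string of length at most 12.
#' @return a [DecodedPath-class].
#' @export
bruteForceDecode <- function(model, seq) {
  si <- .encodeSeq(seq)
  n <- length(si)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  if (n > 12L)
    stop("refused: brute-force enumeration is limited to sequences of at most 12 nt",
         call. = FALSE)
  bin <- gcBin(seq, model)
  S <- .stepMatrix(model, si, bin)
  out <- .outgoingArcs(model@transitions)
  consumes <- .rowConsumes()
  prior <- .logPrior()

  best <- -Inf
  bestPath <- NULL
  cur <- integer(n)

  betterTie <- function(cand) {
    for (i in n:1) {
      if (cand[i] < bestPath[i]) return(TRUE)
      if (cand[i] > bestPath[i]) return(FALSE)
    }
    FALSE
  }
  recurse <- function(e, r, sc) {
    if (e == n) {
      if (sc > best || (sc == best && betterTie(cur))) {
        best <<- sc
        bestPath <<- cur[seq_len(n)]
      }
      return(invisible())
    }
    a <- out[[r]]
    for (k in seq_len(nrow(a))) {
      to <- a[k, "to"]
      kc <- consumes[to]
      e2 <- e + kc
      if (e2 > n) next
      cur[(e + 1L):e2] <<- to
      recurse(e2, to, sc + a[k, "logw"] + S[to, e2])
    }
  }
  for (r in seq_len(.N_ROWS)) {
    kc <- consumes[r]
    if (kc > n) next
    cur[seq_len(kc)] <- r
    recurse(kc, r, prior + S[r, kc])
  }
  new("DecodedPath", states = .ROW_LABELS[bestPath], logScore = unname(best),
      seqLength = n, gcBin = as.integer(bin), opCount = NA_real_)
}
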