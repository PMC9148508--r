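# From decoded paths to gene calls: coordinates, indel bookkeeping, the
# unified indel-annotated DNA representation, renderings and translation.
#
# The annotated DNA of a gene is a single character string from which both
# renderings derive without a second reconstruction pass:
#   uppercase letter  = base decoded in a match or boundary state
#   lowercase letter  = base decoded in an insertion state
#   "-"               = deletion placeholder (a skipped model position)
# formatted rendering  : the annotated string itself (as-read bases with
#                        insertions lowercased and deletions marked "-")
# unformatted rendering: insertion characters dropped, placeholders filled
#                        with "N", everything uppercase -- the
#                        frame-corrected sequence whose length is a codon
#                        multiple when both boundary codons are present.
# The placeholder/fill characters are isolated here for compatibility
# adjustment.
.DELETION_MARK <- "-"
.DELETION_FILL <- "N"

#' Reverse complement of a nucleotide string
#'
#' Standard complement with `N -> N`; case is preserved per base. Characters
#' outside `A C G T N` (either case) are an error.
#'
#' @param seq nucleotide string.
#' @return the reverse-complemented string.
#' @examples
#' revComp("ATGC")   # "GCAT"
#' revComp("AnT")    # "AnT"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTNacgtn]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", seq), "")[[1]]),
        collapse = "")
}

# log-odds of the decoded gene segment against an all-noncoding path over
# the same span; reported per position.
.segmentLogOdds <- function(rows, sPos, S, arcs, tl) {
  g <- 0
  prev <- NA_integer_
  consumes <- .rowConsumes()
  for (pos in seq_along(rows)) {
    # walk step-wise: skip the repeated labels inside composites
    if (pos > 1L && rows[pos] == rows[pos - 1L] &&
        consumes[rows[pos]] == 3L) next
    row <- rows[pos]
    k <- consumes[row]
    end <- sPos + pos - 1L + (k - 1L)
    if (is.na(prev)) {
      w <- if (sPos == 1L) .logPrior() else {
        a <- arcs[[row]]
        a[a[, "from"] == .ROW_R, "logw"][1]
      }
      g <- g + w
    } else {
      a <- arcs[[row]]
      g <- g + a[a[, "from"] == prev, "logw"][1]
    }
    g <- g + S[row, end]
    prev <- row
  }
  span <- seq(sPos, length.out = length(rows))
  r <- sum(S[.ROW_R, span]) + (length(span) - 1L) * tl[["NN"]] +
    if (sPos == 1L) .logPrior() else tl[["NN"]]
  unname((g - r) / length(rows))
}

#' Extract gene calls from a decoded path
#'
#' Converts the state path of one read into gene predictions: one call per
#' maximal run of gene states (boundary composites included in the span).
#' Insertion positions are the input positions decoded in insertion states;
#' deletion positions are the input positions of the base emitted just
#' after a deletion skip. The per-gene score is the mean per-position
#' log-odds of the decoded gene path against an all-noncoding path over the
#' same span. Frame is the codon phase of the gene's first base on its
#' coding strand: `((start - 1) mod 3) + 1` for `+` genes and
#' `((L - end) mod 3) + 1` for `-` genes on a read of length `L`.
#'
#' @param model the [FgsModel-class] used for decoding (needed to score).
#' @param path a [DecodedPath-class] decoded from `seq`.
#' @param seq the decoded nucleotide string.
#' @param readId identifier of the read.
#' @return a [GenomicRanges::GRanges] (seqnames = `readId`, 1-based
#'   inclusive coordinates on the input sequence as given, also for `-`
#'   genes), sorted and non-overlapping, with metadata columns `frame`,
#'   `score`, `inserts` and `deletes` (IntegerList), `annotated` (the
#'   unified indel-annotated DNA, see [renderDna()]), `hasStart`,
#'   `hasStop`. An all-noncoding path yields an empty GRanges.
#' @export
extractGenes <- function(model, path, seq, readId) {
  stopifnot(is(path, "DecodedPath"), nchar(seq) == path@seqLength)
  rows <- match(path@states, .ROW_LABELS)
  n <- length(rows)
  strandOf <- .rowStrand()
  periodOf <- .rowPeriod()
  tag <- ifelse(rows == .ROW_R, "N", strandOf[rows])
  runs <- rle(tag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  emptyGr <- function() {
    gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
      readId, seqlengths = n))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      frame = integer(0), score = numeric(0),
      inserts = IRanges::IntegerList(), deletes = IRanges::IntegerList(),
      annotated = character(0), hasStart = logical(0),
      hasStop = logical(0))
    gr
  }
  gi <- which(runs$values != "N")
  if (length(gi) == 0L) return(emptyGr())

  bases <- strsplit(seq, "")[[1]]
  S <- .stepMatrix(model, .encodeSeq(seq), path@gcBin)
  arcs <- .incomingArcs(model@transitions)

  recs <- lapply(gi, function(j) {
    s <- starts[j]; e <- ends[j]
    segRows <- rows[s:e]
    lab <- path@states[s:e]
    strand <- runs$values[j]
    isIns <- startsWith(lab, "I")
    inserts <- s:e
    inserts <- inserts[isIns]
    deletes <- integer(0)
    for (q in which(!isIns & !startsWith(lab, "S") & !startsWith(lab, "E"))) {
      if (q == 1L) next
      pPrev <- periodOf[segRows[q - 1L]]
      pCur <- periodOf[segRows[q]]
      if (!is.na(pPrev) && !is.na(pCur) && !isIns[q - 1L] &&
          .wrap6(pPrev + 2L) == pCur)
        deletes <- c(deletes, s + q - 1L)
    }
    tokens <- character(0)
    for (q in seq_along(segRows)) {
      pos <- s + q - 1L
      if (pos %in% deletes) tokens <- c(tokens, .DELETION_MARK)
      tokens <- c(tokens, if (isIns[q]) tolower(bases[pos])
                          else toupper(bases[pos]))
    }
    hasStart <- if (strand == "+") "S+" %in% lab else "S-" %in% lab
    hasStop <- if (strand == "+") "E+" %in% lab else "E-" %in% lab
    frame <- if (strand == "+") ((s - 1L) %% 3L) + 1L
             else ((n - e) %% 3L) + 1L
    score <- round(.segmentLogOdds(segRows, s, S, arcs, model@transitions), 6L)
    list(start = s, end = e, strand = strand, frame = frame, score = score,
         inserts = inserts, deletes = deletes,
         annotated = paste(tokens, collapse = ""),
         hasStart = hasStart, hasStop = hasStop)
  })

  gr <- GenomicRanges::GRanges(
    seqnames = readId,
    ranges = IRanges::IRanges(start = vapply(recs, `[[`, 0L, "start"),
                              end = vapply(recs, `[[`, 0L, "end")),
    strand = vapply(recs, `[[`, "", "strand"),
    seqinfo = GenomeInfoDb::Seqinfo(readId, seqlengths = n))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    frame = vapply(recs, `[[`, 0L, "frame"),
    score = vapply(recs, `[[`, 0, "score"),
    inserts = IRanges::IntegerList(lapply(recs, `[[`, "inserts")),
    deletes = IRanges::IntegerList(lapply(recs, `[[`, "deletes")),
    annotated = vapply(recs, `[[`, "", "annotated"),
    hasStart = vapply(recs, `[[`, TRUE, "hasStart"),
    hasStop = vapply(recs, `[[`, TRUE, "hasStop"))
  gr
}

#' Render the DNA of gene calls
#'
#' Both renderings derive from the single annotated representation built by
#' [extractGenes()]. The unformatted (frame-corrected) rendering drops
#' insertion bases and fills each deletion placeholder with `N`; the
#' formatted rendering is the as-read sequence with insertion bases in
#' lowercase and deletion placeholders marked `-`.
#'
#' @param genes a [GenomicRanges::GRanges] from [extractGenes()] (any
#'   subset).
#' @param formatted logical flag selecting the rendering.
#' @return character vector, one sequence per gene.
#' @export
renderDna <- function(genes, formatted = FALSE) {
  ann <- S4Vectors::mcols(genes)$annotated
  cnt <- get0("renderCount", envir = .fgsrCache, ifnotfound = 0)
  assign("renderCount", cnt + length(ann), envir = .fgsrCache)
  if (formatted) return(ann)
  out <- gsub("[a-z]", "", ann)
  toupper(gsub(.DELETION_MARK, .DELETION_FILL, out, fixed = TRUE))
}

#' Translate a frame-corrected gene sequence
#'
#' Translates with the bacterial/archaeal genetic code (translation table
#' 11). For `strand = "-"` the reverse complement is translated, so minus
#' genes passed in forward-read orientation come out right. Any codon
#' containing an ambiguous base translates to `X`, a trailing incomplete
#' codon is dropped, and a terminal stop is removed from the protein. When
#' `hasStart` is `TRUE` an initial ATG/GTG/TTG codon is rendered as `M`
#' (the prokaryotic alternative-start convention); internal codons always
#' use the standard table.
#'
#' @param dna frame-corrected nucleotide string (the unformatted rendering
#'   of [renderDna()]).
#' @param strand `"+"` or `"-"`.
#' @param hasStart does the gene include its start codon?
#' @return amino acid string.
#' @examples
#' translateGene("ATGAAA", "+")   # "MK"
#' translateGene("TTTCAT", "-")   # "MK"
#' @export
translateGene <- function(dna, strand = "+", hasStart = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "-") dna <- revComp(dna)
  dna <- toupper(dna)
  m <- (nchar(dna) %/% 3L) * 3L
  if (m == 0L) return("")
  dna <- substr(dna, 1L, m)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,       # the start-codon rule is applied below
    if.fuzzy.codon = "X"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (hasStart && nchar(aa) >= 1L &&
      substr(dna, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    substr(aa, 1L, 1L) <- "M"
  aa
}
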