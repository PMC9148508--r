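# Viterbi decoding and path scoring.
#
# The compiled DP core (src/viterbi.cpp) and the R-side scoring here state
# the model topology independently; agreement between the two routes is what
# the exhaustive-enumeration oracle tests check.

.BASES <- c("A", "C", "G", "T")

.encodeSeq <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  v <- match(b, .BASES) - 1L
  v[is.na(v)] <- 4L          # every ambiguity code scores as N
  v
}

.flatPeriods <- function(tabs) {
  unlist(lapply(tabs, function(m) as.numeric(t(m))), use.names = FALSE)
}

# context-marginal emission row (uniform weight over the 16 contexts), used
# when the preceding dinucleotide is unavailable (sequence start) or
# contains an ambiguous base
.margRow <- function(tab) log(colMeans(exp(tab)))

.kindIndex <- c(start = 1L, stop = 2L, rev_start = 3L, rev_stop = 4L)
.kindTable <- c(start = "start", stop = "stop",
                rev_start = "rstart", rev_stop = "rstop")

# boundary score on an encoded sequence; `pos` is the 1-based position of
# the first base of the boundary codon.
.boundaryScoreInt <- function(bp, adjust, W, si, pos, kind) {
  tab <- bp[[.kindTable[[kind]]]]
  a <- adjust[kind, ]
  ctr <- pos + 1L
  half <- (W - 1L) %/% 2L
  n <- length(si)
  s <- 0
  for (j in seq_len(W)) {
    q <- ctr + j - 1L - half
    if (q < 1L || q > n) next
    lp <- if (si[q] > 3L) .LOG_UNIF else tab[j, si[q] + 1L]
    s <- s + (W * a[j]) * lp
  }
  s
}

#' Score a candidate start/stop boundary placement
#'
#' Combines the positional weight matrix of the requested boundary kind,
#' evaluated over the window of length W centred on the boundary codon's
#' middle base, with the boundary-adjustment distribution: the log PWM
#' probability at window offset j is weighted by `W * a[j]`, where `a` is
#' the adjustment row for that kind (so a uniform adjustment reproduces the
#' plain PWM log-likelihood). Window offsets falling outside the sequence
#' are skipped, so scores at sequence edges are always finite; ambiguous
#' bases contribute `log(1/4)`.
#'
#' @param model an [FgsModel-class].
#' @param seq nucleotide string.
#' @param pos 1-based position of the first base of the boundary codon.
#' @param kind `"start"`, `"stop"`, `"rev_start"` or `"rev_stop"`.
#' @param bin GC bin used to select the parameter tables.
#' @return log score (numeric scalar).
#' @export
boundaryScore <- function(model, seq, pos, kind,
                          bin = gcBin(seq, model)) {
  if (!kind %in% names(.kindIndex))
    stop(sprintf("unknown boundary kind '%s'; expected one of %s", kind,
                 paste(names(.kindIndex), collapse = ", ")), call. = FALSE)
  si <- .encodeSeq(seq)
  stopifnot(pos >= 1, pos <= length(si))
  .boundaryScoreInt(binParams(model, bin), model@adjust, model@window,
                    si, as.integer(pos), kind)
}

# Per-row step scores on one sequence: S[row, i] is the term a path gains
# when row `row` ends at position i (emission for single-consume rows,
# boundary score for composites). Used by scorePath and the brute-force
# enumerator; the compiled core computes the same quantities inline.
.stepMatrix <- function(model, si, bin) {
  n <- length(si)
  bp <- model@bins[[as.character(bin)]]
  S <- matrix(NA_real_, .N_ROWS, n)
  margs <- list(nc = .margRow(bp$noncoding),
                m = lapply(bp$match, .margRow),
                r = lapply(bp$rmatch, .margRow))
  for (i in seq_len(n)) {
    b <- si[i]
    ctxOK <- i >= 3L && si[i - 1L] < 4L && si[i - 2L] < 4L
    ctx <- if (ctxOK) si[i - 2L] * 4L + si[i - 1L] + 1L else NA_integer_
    emit <- function(tab, marg) {
      if (b > 3L) .LOG_UNIF
      else if (!ctxOK) marg[b + 1L]
      else tab[ctx, b + 1L]
    }
    S[.ROW_R, i] <- emit(bp$noncoding, margs$nc)
    for (p in 1:6) {
      S[.ROW_MF[p], i] <- emit(bp$match[[p]], margs$m[[p]])
      S[.ROW_MR[p], i] <- emit(bp$rmatch[[p]], margs$r[[p]])
    }
    S[.ROW_IF, i] <- .LOG_UNIF
    S[.ROW_IR, i] <- .LOG_UNIF
    if (i >= 3L) {
      for (k in names(.kindIndex)) {
        row <- c(.ROW_SF, .ROW_EF, .ROW_SR, .ROW_ER)[.kindIndex[[k]]]
        S[row, i] <- .boundaryScoreInt(bp, model@adjust, model@window,
                                       si, i - 2L, k)
      }
    }
  }
  S
}

#' DecodedPath: the maximum-probability state path of one sequence
#'
#' @slot states decoding-row label per input position (boundary composites
#'   repeat their label over the three positions they consume).
#' @slot logScore total log score of the path.
#' @slot seqLength number of positions decoded.
#' @slot gcBin GC bin whose parameters were used.
#' @slot opCount number of predecessor evaluations performed by the DP
#'   (instrumentation; grows linearly with sequence length).
#' @seealso [viterbiDecode()], [scorePath()]
#' @export
setClass("DecodedPath", representation(
  states = "character", logScore = "numeric", seqLength = "integer",
  gcBin = "integer", opCount = "numeric"
))

setValidity("DecodedPath", function(object) {
  if (length(object@states) != object@seqLength)
    return("states must have one label per input position")
  if (!all(object@states %in% .ROW_LABELS))
    return("unknown decoding row label")
  TRUE
})

setMethod("show", "DecodedPath", function(object) {
  cat("DecodedPath:", object@seqLength, "nt, log score",
      format(object@logScore, digits = 8), "\n")
  r <- rle(object@states)
  cat(paste0(r$values, "x", r$lengths, collapse = " "), "\n")
})

#' @describeIn viterbiDecode per-position decoding row labels.
#' @param path a [DecodedPath-class].
#' @export
pathStates <- function(path) path@states

#' @describeIn viterbiDecode total log score of the decoded path.
#' @export
pathScore <- function(path) path@logScore

#' Viterbi decoding of one nucleotide sequence
#'
#' Computes the maximum-log-probability state path under the model, using
#' the parameter tables of the sequence's GC bin. Bases other than A, C, G,
#' T (case-insensitive) are treated as fully ambiguous and emit with
#' probability 1/4 under every state, so they carry no coding signal; a
#' position whose preceding dinucleotide context is unavailable (sequence
#' start, or a context containing an ambiguous base) emits from the
#' table's context-marginal distribution; a sequence consisting only of
#' ambiguous bases is reported as entirely noncoding. Paths may begin and end in any state (equal prior over the 29
#' decoding rows) because partial genes truncated at read edges are the
#' tool's core use case. Decoding is deterministic: score ties resolve to
#' the lowest-numbered decoding row.
#'
#' @param model an [FgsModel-class].
#' @param seq nucleotide string (length at least 1).
#' @return a [DecodedPath-class].
#' @examples
#' m <- defaultModel("complete")
#' p <- viterbiDecode(m, "ACGTACGTACGT")
#' pathScore(p)
#' @export
viterbiDecode <- function(model, seq) {
  stopifnot(is(model, "FgsModel"), is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  si <- .encodeSeq(seq)
  bin <- gcBin(seq, model)
  if (all(si > 3L)) {
    # no informative base: report noncoding rather than whatever the
    # transition structure alone would favour
    states <- rep("R", length(si))
    sc <- scorePath(model, seq, states)
    return(new("DecodedPath", states = states, logScore = sc,
               seqLength = length(si), gcBin = as.integer(bin),
               opCount = 0))
  }
  bp <- model@bins[[as.character(bin)]]
  pwmFlat <- unlist(lapply(c("start", "stop", "rstart", "rstop"),
                           function(k) as.numeric(t(bp[[k]]))),
                    use.names = FALSE)
  res <- .viterbiCore(si, .flatPeriods(bp$match), .flatPeriods(bp$rmatch),
                      as.numeric(t(bp$noncoding)),
                      unlist(lapply(bp$match, .margRow), use.names = FALSE),
                      unlist(lapply(bp$rmatch, .margRow), use.names = FALSE),
                      .margRow(bp$noncoding), pwmFlat,
                      model@adjust, model@window,
                      model@transitions[.TRANS_KEYS], .logPrior(),
                      .LOG_UNIF)
  new("DecodedPath", states = .ROW_LABELS[res$path],
      logScore = res$logScore, seqLength = length(si),
      gcBin = as.integer(bin), opCount = res$opCount)
}

#' Score a given state path
#'
#' Accumulates initial, transition, emission and boundary terms for a fully
#' specified path exactly as [viterbiDecode()] accumulates them, making it
#' the reference scorer for the enumeration oracle. Boundary composite
#' labels must appear in runs of exactly three positions.
#'
#' @param model an [FgsModel-class].
#' @param seq nucleotide string.
#' @param states decoding-row label per position (see
#'   `decodingRows(stateInventory(model))`), or a [DecodedPath-class].
#' @return total log score.
#' @export
scorePath <- function(model, seq, states) {
  if (is(states, "DecodedPath")) states <- states@states
  si <- .encodeSeq(seq)
  n <- length(si)
  if (length(states) != n)
    stop("states must have one label per sequence position", call. = FALSE)
  rows <- match(states, .ROW_LABELS)
  if (anyNA(rows))
    stop(sprintf("unknown decoding row label at position %d",
                 which(is.na(rows))[1]), call. = FALSE)
  bin <- gcBin(seq, model)
  S <- .stepMatrix(model, si, bin)
  arcs <- .incomingArcs(model@transitions)
  consumes <- .rowConsumes()
  total <- 0
  i <- 1L; prev <- NA_integer_
  while (i <= n) {
    r <- rows[i]
    k <- consumes[r]
    if (k == 3L) {
      if (i + 2L > n || rows[i + 1L] != r || rows[i + 2L] != r)
        stop(sprintf("boundary composite %s at position %d must span 3 positions",
                     .ROW_LABELS[r], i), call. = FALSE)
    }
    if (is.na(prev)) {
      total <- total + .logPrior()
    } else {
      a <- arcs[[r]]
      hit <- which(a[, "from"] == prev)
      if (length(hit) == 0L)
        stop(sprintf("illegal transition %s -> %s at position %d",
                     .ROW_LABELS[prev], .ROW_LABELS[r], i), call. = FALSE)
      total <- total + a[hit[1L], "logw"]
    }
    total <- total + S[r, i + k - 1L]
    prev <- r
    i <- i + k
  }
  unname(total)
}
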