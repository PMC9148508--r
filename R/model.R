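# Trained model parameters: FGS-format training directories, per-GC-bin
# emission tables, macro transitions, boundary PWMs.
#
# Training-directory dialect (documented field by field):
#   gene, rgene   : per GC bin, a header line holding the integer bin label,
#                   then 96 whitespace-separated rows of 4 probabilities
#                   (A C G T): six codon periods x 16 preceding-dinucleotide
#                   contexts (AA, AC, AG, AT, CA, ... TT; first context base
#                   outermost). gene is the forward-strand coding model,
#                   rgene the reverse-strand one.
#   noncoding     : per bin, 16 context rows of 4 probabilities for the
#                   intergenic state.
#   start, stop,
#   start1, stop1 : per bin, W rows of 4 probabilities; the positional
#                   weight matrix over a window of odd length W centred on
#                   the boundary codon. start/stop are the forward-strand
#                   start/stop codon models; start1/stop1 the reverse-strand
#                   ones (start1 peaks on the reverse complement of a start
#                   codon). W is inferred from the file and must agree
#                   across the four files.
#   pwm           : four labelled rows "start|stop|start1|stop1 w1 .. wW":
#                   the boundary-adjustment distribution per boundary kind,
#                   i.e. relative weights over the W window offsets used
#                   when scoring a candidate boundary placement.
#   <condition>   : one file per error-model condition (e.g. complete,
#                   sanger_5, 454_10, illumina_10) of "KEY value" lines:
#                   NN (noncoding self-loop), NSF (noncoding -> forward
#                   start), NER (noncoding -> reverse gene), MM (codon
#                   advance), MI (insertion open), MD (deletion skip),
#                   II (insertion extend), IM (insertion close), GE (gene
#                   exit branch weight at codon-boundary periods).
#                   {NN,NSF,NER}, {MM,MI,MD} and {II,IM} are distributions.
#
# Every distribution row must sum to 1 within 1e-3 (else a validation
# error); accepted rows are renormalised exactly before the log transform,
# so a loaded model satisfies the 1e-6 normalisation invariant.

.SHARED_FILES <- c("gene", "rgene", "noncoding", "start", "stop",
                   "start1", "stop1", "pwm")
.TRANS_KEYS <- c("NN", "NSF", "NER", "MM", "MI", "MD", "II", "IM", "GE")
.CONTEXTS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             function(a, b) paste0(a, b)))
.BOUNDARY_KINDS <- c("start", "stop", "rev_start", "rev_stop")

#' FgsModel: a full trained parameter set of the gene model
#'
#' Holds one parameter set per integer GC-percentage bin (codon-periodic
#' match emissions for both strands, noncoding emissions, four boundary
#' positional weight matrices) together with the macro transition
#' probabilities of the chosen error-model condition and the
#' boundary-adjustment distributions. All probabilities are kept in log
#' space after loading; probability zero is stored as the finite sentinel
#' `-1e9` so that Viterbi arithmetic never leaves the reals.
#'
#' @slot condition name of the error-model condition (e.g. `"complete"`,
#'   `"454_10"`).
#' @slot transitions named log-probability vector of the macro transitions
#'   (`NN`, `NSF`, `NER`, `MM`, `MI`, `MD`, `II`, `IM`, `GE`).
#' @slot bins named list, one element per GC bin, each holding `match` and
#'   `rmatch` (lists of six 16x4 log emission matrices), `noncoding`
#'   (16x4), and `start`/`stop`/`rstart`/`rstop` (Wx4 log PWMs).
#' @slot binRange integer lower/upper GC bin; lookups clamp to this range.
#' @slot window odd PWM window length W shared by the four boundary tables.
#' @slot adjust 4xW matrix of boundary-adjustment weights (raw
#'   probabilities; rows `start`, `stop`, `rev_start`, `rev_stop`).
#' @seealso [readTrainingSet()], [defaultModel()], [viterbiDecode()]
#' @export
setClass("FgsModel", representation(
  condition = "character", transitions = "numeric", bins = "list",
  binRange = "integer", window = "integer", adjust = "matrix"
))

.rowsNormalised <- function(m, tol = 1e-6) {
  s <- rowSums(exp(m))
  all(abs(s - 1) <= tol)
}

setValidity("FgsModel", function(object) {
  if (!all(.TRANS_KEYS %in% names(object@transitions)))
    return("missing macro transition keys")
  if (any(!is.finite(object@transitions)))
    return("non-finite macro transition")
  keys <- suppressWarnings(as.integer(names(object@bins)))
  if (anyNA(keys) || !identical(sort(keys), seq(min(keys), max(keys))))
    return("gc bins must cover a contiguous integer range")
  if (!identical(object@binRange, range(keys)))
    return("binRange does not match bin keys")
  if (object@window %% 2L != 1L)
    return("boundary window length must be odd")
  for (b in object@bins) {
    for (p in 1:6)
      if (!.rowsNormalised(b$match[[p]]) || !.rowsNormalised(b$rmatch[[p]]))
        return("match emission row not normalised within 1e-6")
    if (!.rowsNormalised(b$noncoding))
      return("noncoding emission row not normalised within 1e-6")
    for (k in c("start", "stop", "rstart", "rstop")) {
      if (nrow(b[[k]]) != object@window)
        return("boundary tables must share the window length")
      if (!.rowsNormalised(b[[k]]))
        return("boundary PWM row not normalised within 1e-6")
    }
  }
  if (!identical(dim(object@adjust), c(4L, as.integer(object@window))))
    return("adjust must be 4 x window")
  if (any(abs(rowSums(object@adjust) - 1) > 1e-6))
    return("adjustment rows must be distributions")
  TRUE
})

setMethod("show", "FgsModel", function(object) {
  cat("FgsModel condition:", object@condition,
      " GC bins:", object@binRange[1], "-", object@binRange[2],
      " window:", object@window, "\n")
})

#' @describeIn readTrainingSet name of the loaded error-model condition.
#' @export
conditionName <- function(model) model@condition

#' @describeIn readTrainingSet integer range of available GC bins.
#' @export
gcBinRange <- function(model) model@binRange

#' @describeIn readTrainingSet parameter tables of one GC bin (clamped
#'   lookup below/above the available range).
#' @param bin integer GC percentage.
#' @export
binParams <- function(model, bin) {
  bin <- max(model@binRange[1], min(model@binRange[2], as.integer(bin)))
  model@bins[[as.character(bin)]]
}

.trimmedLines <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("\r$", "", x)
  x
}

.numTokens <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  suppressWarnings(as.numeric(toks))
}

# Parse one per-GC-bin table file into a named list of numeric matrices.
# `nrowBlock` fixes the number of rows per bin; NULL infers it from the
# first block (used for the boundary PWM files, whose window length is a
# property of the training set).
.parseBinnedFile <- function(path, nrowBlock = NULL, what = basename(path)) {
  lines <- .trimmedLines(path)
  bins <- list()
  cur <- NULL; curKey <- NULL
  flush <- function() {
    if (is.null(curKey)) return()
    m <- do.call(rbind, cur)
    if (!is.null(nrowBlock) && nrow(m) != nrowBlock)
      stop(sprintf("%s: GC bin %s has %d rows, expected %d",
                   what, curKey, nrow(m), nrowBlock), call. = FALSE)
    bins[[curKey]] <<- m
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    vals <- .numTokens(line)
    if (anyNA(vals))
      stop(sprintf("%s, line %d: malformed row", what, i), call. = FALSE)
    if (length(vals) == 1L) {
      if (vals != as.integer(vals))
        stop(sprintf("%s, line %d: GC bin label must be an integer",
                     what, i), call. = FALSE)
      flush()
      curKey <- as.character(as.integer(vals)); cur <- list()
      if (!is.null(bins[[curKey]]))
        stop(sprintf("%s, line %d: duplicate GC bin %s", what, i, curKey),
             call. = FALSE)
    } else {
      if (is.null(curKey))
        stop(sprintf("%s, line %d: probability row before any GC bin label",
                     what, i), call. = FALSE)
      if (length(vals) != 4L)
        stop(sprintf("%s, line %d: expected 4 probabilities, got %d",
                     what, i, length(vals)), call. = FALSE)
      if (abs(sum(vals) - 1) > 1e-3)
        stop(sprintf("%s, line %d: distribution row sums to %.6f",
                     what, i, sum(vals)), call. = FALSE)
      cur[[length(cur) + 1L]] <- vals / sum(vals)
    }
  }
  flush()
  if (length(bins) == 0L)
    stop(sprintf("%s: no GC bin blocks found", what), call. = FALSE)
  nr <- unique(vapply(bins, nrow, 0L))
  if (length(nr) != 1L)
    stop(sprintf("%s: GC bins have differing row counts", what),
         call. = FALSE)
  bins
}

.parsePwmFile <- function(path, window) {
  lines <- .trimmedLines(path)
  out <- matrix(NA_real_, 4L, window,
                dimnames = list(.BOUNDARY_KINDS, NULL))
  fileKeys <- c(start = "start", stop = "stop",
                start1 = "rev_start", stop1 = "rev_stop")
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- strsplit(line, "\\s+")[[1]]
    key <- fileKeys[toks[1]]
    if (is.na(key))
      stop(sprintf("pwm, line %d: unknown boundary kind '%s'", i, toks[1]),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (anyNA(vals) || length(vals) != window)
      stop(sprintf("pwm, line %d: expected %d weights", i, window),
           call. = FALSE)
    if (abs(sum(vals) - 1) > 1e-3)
      stop(sprintf("pwm, line %d: adjustment row sums to %.6f", i, sum(vals)),
           call. = FALSE)
    out[key, ] <- vals / sum(vals)
  }
  if (anyNA(out))
    stop("pwm: missing adjustment row for some boundary kind", call. = FALSE)
  out
}

.parseTransitionFile <- function(path, condition) {
  lines <- .trimmedLines(path)
  vals <- c()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- strsplit(line, "\\s+")[[1]]
    if (length(toks) != 2L)
      stop(sprintf("%s, line %d: expected 'KEY value'", condition, i),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(toks[2]))
    if (is.na(v))
      stop(sprintf("%s, line %d: malformed value", condition, i),
           call. = FALSE)
    vals[toks[1]] <- v
  }
  missing <- setdiff(.TRANS_KEYS, names(vals))
  if (length(missing))
    stop(sprintf("%s: missing transition keys: %s", condition,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (grp in list(c("NN", "NSF", "NER"), c("MM", "MI", "MD"),
                   c("II", "IM"))) {
    s <- sum(vals[grp])
    if (abs(s - 1) > 1e-3)
      stop(sprintf("%s: transition group {%s} sums to %.6f", condition,
                   paste(grp, collapse = ","), s), call. = FALSE)
    vals[grp] <- vals[grp] / s
  }
  if (vals[["GE"]] <= 0 || vals[["GE"]] >= 1)
    stop(sprintf("%s: GE must lie in (0, 1)", condition), call. = FALSE)
  vals[.TRANS_KEYS]
}

.logMat <- function(m, rows = .CONTEXTS) {
  m <- .safeLog(m)
  dimnames(m) <- list(rows, c("A", "C", "G", "T"))
  m
}

.splitPeriods <- function(m) {
  lapply(1:6, function(p) .logMat(m[(p - 1L) * 16L + 1:16, , drop = FALSE]))
}

#' Load an FGS-format training directory
#'
#' Parses the shared emission files (`gene`, `rgene`, `noncoding`, the four
#' boundary PWM files and `pwm`) and the transition file of the named
#' error-model condition into a validated, log-transformed
#' [FgsModel-class]. Parsing is strict: missing files, malformed rows,
#' unknown GC-bin labels and distribution rows off by more than `1e-3` all
#' raise errors naming the file (and line where applicable). See the header
#' of `R/model.R` for the byte-level dialect.
#'
#' @param root path to the training directory.
#' @param condition name of the error-model condition; must match a
#'   transition file inside `root`.
#' @return an [FgsModel-class].
#' @examples
#' dir <- system.file("extdata", "training_synthetic", package = "fgsr")
#' m <- readTrainingSet(dir, "complete")
#' gcBinRange(m)
#' @export
readTrainingSet <- function(root, condition) {
  stopifnot(is.character(root), length(root) == 1L,
            is.character(condition), length(condition) == 1L)
  need <- c(.SHARED_FILES, condition)
  for (f in need) {
    if (!file.exists(file.path(root, f)))
      stop(sprintf("training file not found: %s", file.path(root, f)),
           call. = FALSE)
  }
  gene  <- .parseBinnedFile(file.path(root, "gene"),  96L, "gene")
  rgene <- .parseBinnedFile(file.path(root, "rgene"), 96L, "rgene")
  nonc  <- .parseBinnedFile(file.path(root, "noncoding"), 16L, "noncoding")
  start <- .parseBinnedFile(file.path(root, "start"),  NULL, "start")
  stopT <- .parseBinnedFile(file.path(root, "stop"),   NULL, "stop")
  rstart <- .parseBinnedFile(file.path(root, "start1"), NULL, "start1")
  rstop  <- .parseBinnedFile(file.path(root, "stop1"),  NULL, "stop1")

  W <- nrow(start[[1]])
  for (tab in list(stop = stopT, start1 = rstart, stop1 = rstop)) {
    if (nrow(tab[[1]]) != W)
      stop("boundary PWM files disagree on window length", call. = FALSE)
  }
  if (W %% 2L != 1L)
    stop(sprintf("boundary window length %d must be odd", W), call. = FALSE)

  keys <- names(gene)
  for (tab in list(rgene, nonc, start, stopT, rstart, rstop)) {
    if (!identical(sort(names(tab)), sort(keys)))
      stop("training files disagree on the set of GC bins", call. = FALSE)
  }
  ikeys <- sort(as.integer(keys))
  if (!identical(ikeys, seq(min(ikeys), max(ikeys))))
    stop("gc bins must cover a contiguous integer range", call. = FALSE)

  adjust <- .parsePwmFile(file.path(root, "pwm"), W)
  trans <- .parseTransitionFile(file.path(root, condition), condition)

  posRows <- as.character(seq_len(W))
  bins <- lapply(as.character(ikeys), function(k) {
    list(match = .splitPeriods(gene[[k]]),
         rmatch = .splitPeriods(rgene[[k]]),
         noncoding = .logMat(nonc[[k]]),
         start = .logMat(start[[k]], posRows),
         stop = .logMat(stopT[[k]], posRows),
         rstart = .logMat(rstart[[k]], posRows),
         rstop = .logMat(rstop[[k]], posRows))
  })
  names(bins) <- as.character(ikeys)

  new("FgsModel", condition = condition, transitions = .safeLog(trans),
      bins = bins, binRange = range(ikeys), window = as.integer(W),
      adjust = adjust)
}

.fmtRow <- function(x, digits) paste(formatC(x, digits = digits,
                                             format = "g"), collapse = " ")

#' Write a model back to an FGS-format training directory
#'
#' Inverse of [readTrainingSet()]; probabilities are recovered by
#' exponentiating the stored log values (the zero sentinel maps back to 0).
#' With the default `digits`, a write/read round trip reproduces the
#' original probabilities to well within `1e-9`.
#'
#' @param model an [FgsModel-class].
#' @param dir output directory (created if needed).
#' @param digits significant digits used for formatting.
#' @return `dir`, invisibly.
#' @export
writeTrainingSet <- function(model, dir, digits = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- names(model@bins)
  emit <- function(file, rowsOf) {
    con <- file(file.path(dir, file), "w")
    on.exit(close(con))
    for (k in keys) {
      writeLines(k, con)
      m <- exp(rowsOf(model@bins[[k]]))
      m[m < 1e-300] <- 0
      writeLines(apply(m, 1L, .fmtRow, digits = digits), con)
    }
  }
  emit("gene", function(b) do.call(rbind, b$match))
  emit("rgene", function(b) do.call(rbind, b$rmatch))
  emit("noncoding", function(b) b$noncoding)
  emit("start", function(b) b$start)
  emit("stop", function(b) b$stop)
  emit("start1", function(b) b$rstart)
  emit("stop1", function(b) b$rstop)
  pwmKeys <- c(start = "start", stop = "stop",
               rev_start = "start1", rev_stop = "stop1")
  writeLines(vapply(rownames(model@adjust), function(k) {
    paste(pwmKeys[[k]], .fmtRow(model@adjust[k, ], digits))
  }, ""), file.path(dir, "pwm"))
  tr <- exp(model@transitions)
  writeLines(sprintf("%s %s", names(tr),
                     formatC(tr, digits = digits, format = "g")),
             file.path(dir, model@condition))
  invisible(dir)
}

.defaultTrainingDir <- function() {
  system.file("extdata", "training_synthetic", package = "fgsr",
              mustWork = TRUE)
}

#' Packaged error-model conditions
#'
#' @return character vector of condition names shipped with the package.
#' @export
defaultConditions <- function() {
  setdiff(list.files(.defaultTrainingDir()),
          c(.SHARED_FILES, "PROVENANCE"))
}

#' Embedded default model parameters
#'
#' Returns the packaged default training data for the named error-model
#' condition; no training-directory path is required at call time. The
#' result is identical, field by field, to loading the packaged text files
#' with [readTrainingSet()]. The packaged tables are synthetic (generated
#' by [generateParams()]; see `inst/extdata/training_synthetic/PROVENANCE`).
#'
#' @param condition one of [defaultConditions()], e.g. `"complete"` or a
#'   platform_rate name such as `"454_10"`.
#' @return an [FgsModel-class].
#' @examples
#' m <- defaultModel("complete")
#' conditionName(m)
#' @export
defaultModel <- function(condition) {
  valid <- defaultConditions()
  if (!condition %in% valid)
    stop(sprintf("unknown condition '%s'; valid conditions: %s", condition,
                 paste(sort(valid), collapse = ", ")), call. = FALSE)
  key <- paste0("default:", condition)
  if (is.null(.fgsrCache[[key]]))
    .fgsrCache[[key]] <- readTrainingSet(.defaultTrainingDir(), condition)
  .fgsrCache[[key]]
}

#' GC-content bin of a sequence
#'
#' Computes `round(100 * (#G + #C) / (#A + #C + #G + #T))` (ambiguous bases
#' excluded from numerator and denominator; a sequence without any
#' unambiguous base counts as 50) and clamps the result into the model's
#' available bin range, so every sequence selects a parameter set.
#'
#' @param seq a nucleotide string.
#' @param model an [FgsModel-class] supplying the clamp range; omit to get
#'   the unclamped integer percentage.
#' @return integer GC bin.
#' @examples
#' gcBin("ATGC")   # 50
#' @export
gcBin <- function(seq, model = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  b <- strsplit(toupper(seq), "")[[1]]
  gc <- sum(b == "G" | b == "C")
  acgt <- gc + sum(b == "A" | b == "T")
  pct <- if (acgt == 0L) 50L else as.integer(round(100 * gc / acgt))
  if (is.null(model)) return(pct)
  max(model@binRange[1], min(model@binRange[2], pct))
}
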