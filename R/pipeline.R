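# FGS-compatible command line and the parallel, order-preserving pipeline.

.usageText <- paste(
  "usage: fgsr -s <seq_file|-> -o <output_base|-> [-w 0|1] [-t condition]",
  "            [-p workers] [-r train_dir] [-m meta] [-n dna] [-a protein] [-u]",
  sep = "\n")

.fgsUsageError <- function(msg) {
  stop(structure(class = c("fgsUsageError", "error", "condition"),
                 list(message = paste0(msg, "\n", .usageText), call = NULL)))
}

#' Parse FGS-style command line arguments
#'
#' Understands the FGS flag set: `-s` input FASTA (`-` for stdin), `-o`
#' output base path (`-` for stdout; sinks derive as `base.out`,
#' `base.ffn`, `base.faa`), `-w` 0 (short reads) or 1 (complete genome),
#' `-t` error-model condition, `-p` worker count, `-r` custom training
#' directory (defaults to the embedded training data), `-m`/`-n`/`-a`
#' individual metadata/DNA/protein sinks, `-u` unordered output. At least
#' one output product must be resolvable from `-o`/`-m`/`-n`/`-a`.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return an `FgsOptions` list (classed).
#' @examples
#' opts <- parseFgsArgs(c("-s", "in.fa", "-o", "out", "-w", "0",
#'                        "-t", "complete"))
#' opts$sinks
#' @export
parseFgsArgs <- function(argv) {
  opts <- list(seqSource = NULL, outputBase = NULL, wholeGenome = 0L,
               condition = "complete", workers = 1L, trainRoot = NULL,
               metaSink = NULL, dnaSink = NULL, proteinSink = NULL,
               unordered = FALSE)
  valueFlags <- c(s = "seqSource", o = "outputBase", w = "wholeGenome",
                  t = "condition", p = "workers", r = "trainRoot",
                  m = "metaSink", n = "dnaSink", a = "proteinSink")
  i <- 1L
  while (i <= length(argv)) {
    arg <- argv[i]
    if (identical(arg, "-u")) {
      opts$unordered <- TRUE
      i <- i + 1L
      next
    }
    key <- sub("^-", "", arg)
    if (!startsWith(arg, "-") || !key %in% names(valueFlags))
      .fgsUsageError(sprintf("unknown option '%s'", arg))
    if (i + 1L > length(argv))
      .fgsUsageError(sprintf("option %s requires a value", arg))
    opts[[valueFlags[[key]]]] <- argv[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$seqSource))
    .fgsUsageError("missing required option -s")
  if (!opts$wholeGenome %in% c("0", "1", 0L, 1L))
    .fgsUsageError("-w must be 0 (short reads) or 1 (complete genome)")
  opts$wholeGenome <- as.integer(opts$wholeGenome)
  w <- suppressWarnings(as.integer(opts$workers))
  if (is.na(w) || w < 1L)
    .fgsUsageError("-p must be a positive integer")
  opts$workers <- w
  if (is.null(opts$outputBase) && is.null(opts$metaSink) &&
      is.null(opts$dnaSink) && is.null(opts$proteinSink))
    .fgsUsageError("no output sink: give -o or at least one of -m/-n/-a")
  if (is.null(opts$trainRoot) &&
      !opts$condition %in% defaultConditions())
    .fgsUsageError(sprintf(
      "unknown condition '%s'; packaged conditions: %s", opts$condition,
      paste(sort(defaultConditions()), collapse = ", ")))
  opts$sinks <- .resolveSinks(opts)
  class(opts) <- "FgsOptions"
  opts
}

# -o base yields base.out/base.ffn/base.faa (or stdout for "-");
# -m/-n/-a override or add individual sinks.
.resolveSinks <- function(opts) {
  sinks <- list(metadata = NULL, dna = NULL, protein = NULL)
  if (!is.null(opts$outputBase)) {
    if (identical(opts$outputBase, "-")) {
      sinks <- list(metadata = "-", dna = "-", protein = "-")
    } else {
      sinks <- list(metadata = paste0(opts$outputBase, ".out"),
                    dna = paste0(opts$outputBase, ".ffn"),
                    protein = paste0(opts$outputBase, ".faa"))
    }
  }
  if (!is.null(opts$metaSink)) sinks$metadata <- opts$metaSink
  if (!is.null(opts$dnaSink)) sinks$dna <- opts$dnaSink
  if (!is.null(opts$proteinSink)) sinks$protein <- opts$proteinSink
  sinks
}

# Decode one read and render only the requested products.
.processRead <- function(model, id, seq, need) {
  path <- viterbiDecode(model, seq)
  genes <- extractGenes(model, path, seq, id)
  rec <- list(id = id)
  if (need["metadata"]) rec$meta <- .formatMetadata(id, genes)
  if (need["dna"] || need["protein"]) {
    if (length(genes)) {
      headers <- .geneHeaders(id, genes)
      dna <- renderDna(genes, formatted = FALSE)
      if (need["dna"]) rec$ffn <- .fastaLines(headers, dna)
      if (need["protein"]) {
        mc <- S4Vectors::mcols(genes)
        prot <- vapply(seq_along(genes), function(k)
          translateGene(dna[k],
                        as.character(GenomicRanges::strand(genes))[k],
                        hasStart = mc$hasStart[k]), "")
        rec$faa <- .fastaLines(headers, prot)
      }
    } else {
      if (need["dna"]) rec$ffn <- character(0)
      if (need["protein"]) rec$faa <- character(0)
    }
  }
  rec
}

#' Run the gene-calling pipeline
#'
#' Loads the model once (embedded defaults, or a custom training directory
#' via `-r`), reads FASTA from the input source, decodes every read with
#' the GC-bin-appropriate parameters, and writes the selected output
#' products. Unselected products are never computed. Reads are dispatched
#' to `workers` forked processes as individual work units and results are
#' emitted in input order for any worker count; `-u` (unordered) merely
#' relaxes the ordering guarantee. Whole-genome mode (`-w 1`) decodes each
#' record as one sequence and differs only in its expectation of long
#' sequences. On error, file sinks created by the run are removed.
#'
#' @param opts an `FgsOptions` object from [parseFgsArgs()].
#' @return invisibly `0L` on success (errors raise conditions).
#' @export
runPipeline <- function(opts) {
  stopifnot(inherits(opts, "FgsOptions"))
  model <- if (!is.null(opts$trainRoot))
    readTrainingSet(opts$trainRoot, opts$condition)
  else defaultModel(opts$condition)

  reads <- readFasta(opts$seqSource)
  ids <- if (length(reads)) readIds(reads) else character(0)
  if (anyDuplicated(ids))
    message("note: duplicated read ids in input")
  seqs <- as.character(reads)

  sinks <- opts$sinks
  need <- !vapply(sinks, is.null, TRUE)

  conns <- list()
  createdFiles <- character(0)
  ok <- FALSE
  on.exit({
    for (cn in conns) if (!identical(cn, stdout())) close(cn)
    if (!ok && length(createdFiles)) unlink(createdFiles)
  })
  for (nm in names(sinks)) {
    s <- sinks[[nm]]
    if (is.null(s)) next
    if (identical(s, "-")) {
      conns[[nm]] <- stdout()
    } else {
      conns[[nm]] <- tryCatch(suppressWarnings(file(s, "w")),
                              error = function(e)
        stop(sprintf("cannot write to %s sink '%s': %s", nm, s,
                     conditionMessage(e)), call. = FALSE))
      createdFiles <- c(createdFiles, s)
    }
  }

  useFork <- opts$workers > 1L && .Platform$OS.type == "unix"
  # keep forked children short-lived: each one touches (and therefore
  # copies) only a small slice of the parent heap
  chunkSize <- if (useFork) min(512L, 16L * opts$workers) else 500L
  if (useFork) gc(FALSE)
  idx <- seq_along(seqs)
  for (chunk in split(idx, ceiling(idx / chunkSize))) {
    recs <- if (useFork) {
      parallel::mclapply(chunk, function(k)
        .processRead(model, ids[k], seqs[k], need),
        mc.cores = opts$workers, mc.preschedule = TRUE)
    } else {
      lapply(chunk, function(k) .processRead(model, ids[k], seqs[k], need))
    }
    for (r in recs) if (inherits(r, "try-error") || inherits(r, "condition"))
      stop(conditionMessage(attr(r, "condition") %||% r), call. = FALSE)
    writeOutputs(recs, conns[!vapply(conns, is.null, TRUE)])
  }
  ok <- TRUE
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Thin wrapper used by the installed `fgsr` script: parses `argv`, runs
#' the pipeline, and maps errors to exit codes (0 success, 1 data error,
#' 2 usage error) with messages on standard error. Data always goes to
#' standard output, diagnostics never do.
#'
#' @param argv character vector of command line arguments.
#' @return integer exit status.
#' @export
fgsrMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  tryCatch({
    runPipeline(parseFgsArgs(argv))
    0L
  }, fgsUsageError = function(e) {
    message(conditionMessage(e))
    2L
  }, error = function(e) {
    message("fgsr: ", conditionMessage(e))
    1L
  })
}
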