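# FASTA ingest and the three output products (metadata / gene DNA /
# protein) in FGS-compatible layouts.
#
# Metadata (.out) layout: per read a ">read_id" line, then one
# tab-separated line per gene:
#   start  end  strand  frame  score  I:<comma list>  D:<comma list>
# with 1-based inclusive coordinates, strand "+"/"-", frame 1..3, score to
# six decimals, and the insertion/deletion position lists prefixed "I:" and
# "D:" (empty lists render as a bare prefix). Gene DNA (.ffn) and protein
# (.faa) sinks are FASTA with headers ">read-id_start_end_strand" and one
# line per sequence (no wrapping).

#' Read FASTA sequences
#'
#' Reads nucleotide FASTA from a file path, a gzip-compressed file
#' (detected transparently), `"-"` for standard input, or an open
#' connection. Headers are preserved in full as the element names; record
#' sequences split over multiple lines are joined and uppercased on
#' ingest; CRLF line endings and blank lines are tolerated. There is no
#' sequence length cap: whole genomes read fine.
#'
#' @param source path, `"-"`, or a connection.
#' @return a [Biostrings::DNAStringSet], names holding the full headers
#'   (without `>`); see [readIds()] for the whitespace-delimited ids.
#' @export
readFasta <- function(source) {
  opened <- FALSE
  if (inherits(source, "connection")) {
    con <- source
  } else if (identical(source, "-")) {
    con <- file("stdin")
  } else {
    if (!file.exists(source))
      stop(sprintf("cannot read FASTA: no such file '%s'", source),
           call. = FALSE)
    con <- gzfile(source)   # transparent for uncompressed files too
    opened <- TRUE
  }
  lines <- readLines(con, warn = FALSE)
  if (opened) close(con)
  lines <- sub("\r$", "", lines)

  headers <- character(0)
  seqs <- character(0)
  chunks <- character(0)
  curHeader <- NULL
  flush <- function() {
    if (is.null(curHeader)) return()
    s <- paste(chunks, collapse = "")
    if (!nzchar(s))
      stop(sprintf("empty FASTA record: %s", curHeader), call. = FALSE)
    headers[length(headers) + 1L] <<- curHeader
    seqs[length(seqs) + 1L] <<- toupper(s)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush()
      curHeader <- sub("^>", "", line)
      if (!nzchar(trimws(curHeader)))
        stop(sprintf("FASTA format error at line %d: empty header", i),
             call. = FALSE)
      chunks <- character(0)
    } else {
      if (is.null(curHeader))
        stop(sprintf("FASTA format error at line %d: expected '>'", i),
             call. = FALSE)
      if (grepl("[^A-Za-z]", line))
        stop(sprintf("FASTA format error at line %d: invalid sequence character",
                     i), call. = FALSE)
      chunks[length(chunks) + 1L] <- line
    }
  }
  flush()
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- headers
  out
}

#' @describeIn readFasta first whitespace-delimited token of each header.
#' @param x a named [Biostrings::DNAStringSet] as returned by `readFasta`.
#' @export
readIds <- function(x) sub("\\s.*$", "", names(x))

#' Write sequences as single-line FASTA
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path file path or connection.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

.formatScore <- function(x) sprintf("%.6f", x)

# metadata lines of one read
.formatMetadata <- function(id, genes) {
  out <- paste0(">", id)
  if (length(genes)) {
    mc <- S4Vectors::mcols(genes)
    out <- c(out, sprintf(
      "%d\t%d\t%s\t%d\t%s\tI:%s\tD:%s",
      GenomicRanges::start(genes), GenomicRanges::end(genes),
      as.character(GenomicRanges::strand(genes)), mc$frame,
      .formatScore(mc$score),
      vapply(mc$inserts, function(v) paste(v, collapse = ","), ""),
      vapply(mc$deletes, function(v) paste(v, collapse = ","), "")))
  }
  out
}

.geneHeaders <- function(id, genes) {
  sprintf(">%s_%d_%d_%s", id, GenomicRanges::start(genes),
          GenomicRanges::end(genes),
          as.character(GenomicRanges::strand(genes)))
}

# interleave headers and sequences into FASTA lines
.fastaLines <- function(headers, seqs) {
  if (length(headers) == 0L) return(character(0))
  as.vector(rbind(headers, seqs))
}

#' Write the output products of processed reads
#'
#' Streams pre-rendered per-read output to the selected sinks in record
#' order. A sink is a file path, `"-"` for standard output, or an open
#' connection; `NULL` sinks are skipped. Records are lists with elements
#' `meta`, `ffn`, `faa` (character vectors of pre-formatted lines; may be
#' absent when the product was not computed).
#'
#' @param records list of per-read records, in output order.
#' @param sinks named list with optional elements `metadata`, `dna`,
#'   `protein`.
#' @return invisibly `TRUE`.
#' @export
writeOutputs <- function(records, sinks) {
  stopifnot(any(!vapply(sinks, is.null, TRUE)))
  conns <- list()
  opened <- character(0)
  on.exit(for (cn in conns) if (!identical(cn, stdout())) close(cn))
  getCon <- function(name) {
    s <- sinks[[name]]
    if (is.null(s)) return(NULL)
    if (inherits(s, "connection")) return(s)
    if (identical(s, "-")) return(stdout())
    cn <- tryCatch(suppressWarnings(file(s, "w")), error = function(e)
      stop(sprintf("cannot write to %s sink '%s': %s", name, s,
                   conditionMessage(e)), call. = FALSE))
    conns[[name]] <<- cn
    cn
  }
  mcon <- getCon("metadata"); dcon <- getCon("dna"); pcon <- getCon("protein")
  for (rec in records) {
    if (!is.null(mcon) && !is.null(rec$meta)) writeLines(rec$meta, mcon)
    if (!is.null(dcon) && !is.null(rec$ffn)) writeLines(rec$ffn, dcon)
    if (!is.null(pcon) && !is.null(rec$faa)) writeLines(rec$faa, pcon)
  }
  invisible(TRUE)
}
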