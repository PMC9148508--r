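Package: fgsr
Title: Gene Prediction in Short Error-Prone Reads with a Codon-Periodic Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts complete and partial protein-coding regions in short
    sequencing reads and whole prokaryotic genomes using the FragGeneScan
    hidden Markov model: six codon-periodic match states per strand with
    insertion states and implicit deletion skips for sequencing errors,
    three-base start/stop boundary composites scored by positional weight
    matrices, and a single noncoding state. Provides strict parsers for
    FGS-format training directories with per-GC-bin parameter tables,
    exact Viterbi decoding with a unified indel-annotated backtracking
    representation, FASTA input/output with independently selectable
    metadata/DNA/protein sinks, an FGS-compatible command line, and a
    synthetic-data generator with an exhaustive brute-force decoder for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
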