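# fgsr — gene prediction in short reads with a codon-periodic HMM

`fgsr` finds complete and partial protein-coding regions in short,
error-prone sequencing reads and in whole prokaryotic genomes. It
implements the FragGeneScan gene-prediction model: a hidden Markov model
that combines

* **codon usage bias** — six inhomogeneous match states per strand, one
  emission table `P(base | preceding dinucleotide)` per codon period;
* **start/stop codon patterns** — 3-base boundary composites scored by
  positional weight matrices over a window centred on the boundary codon;
* **sequencing-error models** — insertion states and implicit deletion
  skips whose rates are the per-platform error condition (`complete`,
  `sanger_5`, `454_10`, `illumina_10`, ...).

The model has a fixed 49 states; decoding is exact Viterbi over 29
dynamic-programming rows, `O(s²·n)` — linear in sequence length — with
parameters selected per read by integer GC-content bin. Backtracking
produces, per gene, metadata (coordinates, strand, frame, score, indel
positions), a unified indel-annotated DNA representation from which both
the as-read and the frame-corrected renderings derive, and the protein
translation (bacterial code, table 11) — so the emitted DNA always
translates to the emitted protein, on both strands.

It is intended for metagenomics practitioners who would otherwise run
FragGeneScan: the command line is FGS-compatible and reads/writes the
same file conventions (FASTA in, `.out`/`.ffn`/`.faa` out, FGS-format
training directories).

## Worked example

```r
library(fgsr)

model <- defaultModel("complete")      # embedded training data
reads <- generateReads(model, n = 5, length = 300, seed = 1)
s     <- as.character(reads$seqs[[1]])

path  <- viterbiDecode(model, s)
genes <- extractGenes(model, path, s, "read_00001")
genes
#> GRanges object with 1 range and 7 metadata columns:
#>         seqnames    ranges strand |     frame     score       inserts
#>            <Rle> <IRanges>  <Rle> | <integer> <numeric> <IntegerList>
#>   [1] read_00001    44-280      + |         2  0.689797
#>             deletes              annotated  hasStart   hasStop
#>   [1]               ATGAGTATGATGATGACGAG..      TRUE      TRUE
```

One complete gene (start and stop codon present) was called on positions
44–280 of the read, forward strand, frame 2, with no insertions or
deletions; the score (0.69) is the mean per-position log-odds of the gene
path against noncoding — higher means stronger coding signal.
`renderDna(genes)` returns the frame-corrected DNA
(`"ATGAGTATGATGATGACGAGGATGATGGTG..."`) and
`translateGene(renderDna(genes)[1], "+")` its protein
(`"MSMMMTRMMVMVMVIMIMMI..."`).

From the shell (the `exec/fgsr` script is installed with the package):

```sh
fgsr -s reads.fa -o calls -w 0 -t complete -p 4      # all three outputs
fgsr -s - -o - -w 0 -t complete -a proteins.faa      # stdin/stdout pipes
fgsr -s genome.fa -o genome -w 1 -t complete         # complete genome
fgsr -s reads.fa -o calls -r my_train_dir -t 454_10  # custom training data
```

Output products can be selected individually (`-m` metadata, `-n` DNA,
`-a` protein); unselected products are never computed. Results are
emitted in input order for any worker count (`-p`); `-u` relaxes the
ordering guarantee.

Note: the embedded default training tables are **synthetic** (generated,
seed-fixed; see `inst/extdata/training_synthetic/PROVENANCE`). They make
the tool self-contained and testable; for biological use pass a real FGS
training directory via `-r`.

## Package layout

| where | what |
|---|---|
| `R/model.R` | `FgsModel` S4 class, FGS-format training parsers/writer, GC binning, embedded defaults |
| `R/states.R` | state inventory (49-state counting convention) and decoding topology |
| `R/viterbi.R`, `src/viterbi.cpp` | Viterbi decoding (compiled kernel), path scoring, boundary scoring |
| `R/backtrack.R` | gene extraction to `GRanges`, annotated-DNA renderings, translation |
| `R/io.R` | FASTA ingest (file/gzip/stdin), `.out`/`.ffn`/`.faa` writers |
| `R/pipeline.R`, `exec/fgsr` | FGS-compatible CLI and parallel pipeline |
| `R/fixtures.R` | synthetic parameter/read generators with ground truth; brute-force decoding oracle |
| `vignettes/gene-calling-model.Rmd` | the model, its assumptions and design choices |
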