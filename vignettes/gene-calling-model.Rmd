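---
title: "The fgsr gene-calling model: states, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fgsr gene-calling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgsr)
```

## The problem

Shotgun metagenomic sequencing yields short, error-prone reads from mixed
microbial communities. Downstream profiling needs the protein-coding
fragments on those reads, but most reads carry only part of a gene —
missing start or stop codons — and sequencing errors insert or delete
bases, shifting the reading frame. `fgsr` implements the FragGeneScan
model for this task: a hidden Markov model whose states encode codon
periodicity, gene boundaries, sequencing-error indels and intergenic
sequence, decoded exactly by the Viterbi algorithm. It works both on short
reads and on complete genomes.

## The model

The model has 49 hidden states under the following counting convention:

* **Match states** `M1..M6` on each strand (12): two consecutive codons of
  a gene. Emissions are inhomogeneous — each period has its own
  distribution `P(base | preceding dinucleotide)`, which is where codon
  usage bias enters.
* **Insertion states** `I1..I6` per strand (12): a sequencing-error base
  inserted between two codon positions. Insertions emit uniformly (the
  error process carries no codon signal) and hold the period counter.
* **Deletion states** `D1..D6` per strand (12): a skipped model position.
  These are realised *implicitly* as skip transitions `M_p -> M_{p+2}`
  that consume one base while advancing the period by one extra; they
  appear in the state inventory but occupy no row of the DP table.
* **Noncoding state** `R` (1) with its own context-dependent emission
  table.
* **Boundary composites** (4 x 3 = 12 counted base-wise): start and stop
  codons on each strand are 3-base units entered atomically and scored by
  a positional weight matrix (PWM) over a window of odd length W centred
  on the codon, weighted by a per-kind *boundary-adjustment* distribution:
  the log-PWM term at window offset j is multiplied by `W * a[j]`. With a
  uniform adjustment this is the plain PWM log-likelihood; the adjustment
  row is the documented hook for re-weighting candidate boundary
  placements. Window offsets outside the sequence are skipped, so
  boundary scores at read edges are always finite.

A reverse-strand gene appears on the forward reading as reverse-stop
composite, mirrored codons, reverse-start composite. The DP therefore
works over 29 rows (12 match + 12 insertion + 1 noncoding + 4 composites);
with the deletion states and base-wise composite counting the model size
is the fixed s = 49, so Viterbi runs in `O(s^2 n)` — linear in sequence
length, which the test suite asserts by operation counting rather than
wall clock.

Reads may begin and end in any state: partial genes truncated at read
edges are the core use case, so the initial distribution is uniform over
the 29 decoding rows (composites only as a whole).

## Parameters and training data

Parameters live in FGS-format text directories: per-GC-bin tables `gene`,
`rgene`, `noncoding`, the boundary PWMs `start`, `stop`, `start1`,
`stop1`, the adjustment file `pwm`, and one transition file per
error-model condition (`complete`, `sanger_5`, `454_10`, ...; MI and MD —
the insertion/deletion rates — are what distinguishes conditions). The
integer GC bin of each input sequence (`round(100 * GC)` over unambiguous
bases, clamped to the trained range so every sequence decodes) selects the
table set. Parsing is strict and every distribution row is validated to
sum to 1 within `1e-3`, then renormalised exactly; probabilities are kept
in log space, with zero mapped to the finite sentinel `-1e9` so DP
arithmetic stays in the reals.

The packaged default tables under `inst/extdata/training_synthetic/` are
**synthetic** — generated by `generateParams()` with a fixed seed (see the
`PROVENANCE` file there). They make the tool runnable out of the box and
give the parsers a packaged reference, but they are not trained on real
genomes; pass a real FGS training directory with `-r` /
`readTrainingSet()` for biological use.

Key tunable quantities (defaults of the generator, per the packaged set):

| quantity | meaning | default |
|---|---|---|
| `NSF`, `NER` | noncoding -> gene entry probability per strand per base | 0.005 |
| `GE` | gene exit branch weight at codon-boundary periods; mean gene length is about `3/GE` bases | 0.01 |
| `MI`, `MD` | per-base insertion / deletion rates (the error condition) | condition-specific |
| `II` | insertion extension probability | 0.2 |
| `W` | boundary PWM window length (odd) | 5 |
| GC bins | trained range, clamped lookup | 42–58 |

## Numerical and structural choices

Several choices were genuinely open; they are fixed as follows and the
reasoning documented here.

**Gene exit as a branch weight.** The interior transition row
`{MM, MI, MD}` is an exact distribution; the stop-entry weight `GE` at
codon-boundary periods is applied *without* renormalising the interior
row. Viterbi only compares path scores, so the mild unnormalisation is
harmless, and it keeps path scores strand-symmetric (a `(1-GE)`
renormalisation breaks mirror equality whenever a deletion skip crosses a
codon boundary).

**Symmetric attachment costs.** The cost that ties a segment into its
surroundings is split evenly over the segment's entry and exit arcs:
insertion runs pay `sqrt(MI*IM)` on each side, boundary composites pay
`GE/2` on each gene-side arc and `sqrt(NSF*NER)/2`-equivalents on each
noncoding-side arc. Interior segments keep their natural totals; only
segments truncated at a read edge are priced differently, and for those
the symmetric split is the principled choice — it makes decoding a read
and its reverse complement give exactly mirrored paths with equal scores,
which the test suite verifies to `1e-9`.

**Tie-breaking.** When two predecessors of a DP cell tie, the
lowest-numbered row (in the documented row order) wins, and the final row
is the lowest row attaining the maximum. This makes decoding fully
deterministic; the brute-force enumerator reproduces the same rule by
reverse-lexicographic path comparison.

**Ambiguous bases.** `N` (and any other IUPAC ambiguity code) emits with
probability 1/4 under every state, so it carries no coding signal. A
position whose preceding dinucleotide context is unavailable (sequence
start, or a context containing `N`) emits from the table's
context-marginal distribution rather than uniformly — this is both the
natural marginalisation and necessary for exact strand symmetry. A
sequence consisting only of ambiguous bases is reported entirely
noncoding.

**Boundary window pricing.** The composite's PWM term covers all W window
offsets, while offsets outside the codon are also emitted by neighbouring
states. A wide window therefore taxes composites by roughly the
background likelihood of the overlap, which biases decoding toward
edge-partial genes when flanks are short. The default window is kept
narrow (W = 5) so this artifact is negligible; the machinery is generic in
W and the adjustment distribution can down-weight flank offsets for wider
windows.

**Indel topology constraints.** Deletions cannot remove the first or last
interior base of a gene, cannot be adjacent, and cannot immediately follow
an insertion; insertions cannot follow the final interior base. These are
consequences of the skip-arc topology, and the read simulator respects
them so that simulated truth is always representable.

**Output conventions.** Coordinates are 1-based inclusive on the input
sequence as given (forward coordinates also for minus-strand genes);
frame is the codon phase of the gene's first base on its coding strand.
The per-gene score — which the original tool never defines — is the mean
per-position log-odds of the decoded gene path against an all-noncoding
path over the same span, printed to six decimals. The deletion
placeholder is `-` in the formatted rendering and is filled with `N` in
the frame-corrected rendering; both renderings derive from one annotated
string (lowercase = inserted base, `-` = skipped position), so the DNA
and its translation can never disagree: the protein output is the
translation (table 11, `N`-codon to `X`, terminal stop dropped,
alternative initial starts rendered `M` when the start codon is present)
of exactly the emitted frame-corrected DNA.

## The synthetic-data generator

`generateParams()` builds valid normalised parameter sets from a seed
(R's Mersenne-Twister with fixed normal/sample kinds, so fixtures are
byte-stable). Gene emissions are a mixture
`(1-w) * noncoding + w * sharp` with `w = s/(1+s)` for gene strength `s`:
at `s -> 0` coding and noncoding coincide, at large `s` codon bias is
strong and the start/stop PWMs peak on ATG/TAA. In `symmetric` mode the
tables are context-free, 3-periodic and exactly complement-mirrored
between strands, which is what makes the strand-symmetry checks exact. In
asymmetric mode every context row is an independent draw.

The symmetric sharp component is constructed, not merely drawn, so that
"high gene strength" reliably means a decodable codon signal: the three
codon positions get *distinct* dominant nucleotides (a table whose
positions share a dominant base is aperiodic no matter how sharp each row
is), each dominant carries 0.85–0.97 of its row's mass, T is suppressed
at codon position 1 (coding statistics deplete in-frame stop codons,
which is what anchors gene ends), and the noncoding composition is kept
at a moderate AT/GC skew (extreme skews breed spurious stop trigrams in
flanks). Without these constraints a sizeable fraction of random draws
yields models whose maximum-likelihood path legitimately disagrees with
the planted truth — a property of the draw, not of the decoder.

`generateReads()` samples reads from the model's own generative process —
noncoding flanks, one planted gene (a canonical ATG start, periodic
interior codons, a canonical TAA stop; minus-strand genes as reverse
complements), per-base indels inside the gene interior at stated rates —
and records ground truth exactly, in the same position conventions the
decoder reports. Boundary codons are planted canonically because starts
and stops are discrete biological signals; sampling them from the
smoothed PWM would manufacture genes with intrinsically unanchorable
boundaries. The boundary-recovery experiment runs at gene strength 20
with the codon-only window (W = 3, avoiding the window-pricing artifact
above) on error-free 300 bp reads.

What the fixtures do *not* emulate: real codon usage tables, GC-dependent
parameter variation (all bins share one table set), platform-specific
error profiles (indels are uniform i.i.d.), overlapping genes and genes
sharing boundaries (the topology requires at least one noncoding base
between genes), and translated-BLAST-style validation. Passing tests
therefore demonstrate that the implementation decodes its own model
exactly and handles errors and boundaries correctly — not that the
packaged synthetic tables predict genes well on real reads; for that, use
real training data.

## Problem sizes used in the checks

The structural checks are instant. The enumeration oracle compares
Viterbi with exhaustive path enumeration on 200+ random model/sequence
pairs of length up to 12 (enumeration is exponential, which is why the
oracle refuses longer input). Self-consistency is verified on simulated
error-containing reads and on a ~100 kb synthetic genome decoded in
whole-genome mode. Concurrency checks run 1000 simulated reads with 1, 8
and 16 workers; boundary recovery uses 100 error-free 300 bp reads at
gene strength 20, requiring both boundaries within ±3 bases on at least
95 of them. These sizes were chosen to exercise every code path at
comfortable margins.

## Limitations

* The packaged training tables are synthetic (see above).
* The exact byte format of FGS training files and `.out` metadata is
  pinned from convention, not from a normative specification; the parser
  and writers document every field and isolate the choices
  (placeholder characters, strand symbols) for compatibility adjustment.
* The score column is this package's own definition and is not promised
  to match the original tool's printed scores.
* Only Viterbi decoding is provided; no posterior/forward–backward
  probabilities.
* Two genes cannot abut directly; at least one noncoding base must
  separate them.

## A worked call

```{r example, eval = FALSE}
model <- defaultModel("complete")
reads <- generateReads(model, n = 5, length = 300, seed = 1)
s <- as.character(reads$seqs[[1]])
path <- viterbiDecode(model, s)
genes <- extractGenes(model, path, s, "read_00001")
genes
renderDna(genes)                   # frame-corrected DNA
translateGene(renderDna(genes)[1],
              as.character(GenomicRanges::strand(genes))[1])
```

From the shell, the installed `fgsr` script is a drop-in FGS-style
interface:

```sh
fgsr -s reads.fa -o calls -w 0 -t complete -p 4
# calls.out (metadata), calls.ffn (gene DNA), calls.faa (proteins)
```
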