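Synthetic default training data
===============================

These tables are NOT trained on real genomes. They were produced by the
package's own fixture generator and are shipped so that the tool runs out
of the box (embedded defaults, no -r needed) and so that the parsers have
a packaged reference. Replace them with a real FGS training directory via
the -r option / readTrainingSet() for biological use.

Generated with, for each (condition, insertRate, deleteRate) in
  complete 1e-4 1e-4; sanger_5 .0025 .0025; sanger_10 .005 .005;
  454_10 .005 .005; 454_30 .015 .015; illumina_5 .0025 .0025;
  illumina_10 .005 .005:

  m <- generateParams(20260925, symmetric = TRUE, geneStrength = 4,
                      condition = cond, insertRate = ins, deleteRate = del,
                      binRange = c(42L, 58L), window = 5L)
  writeTrainingSet(m, "training_synthetic", digits = 5L)

Condition names follow the FGS convention (platform_rate); MI = MD = half
the percent error rate the name implies.
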