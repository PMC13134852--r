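Package: offtargetr
Title: Off-Target Binding Prediction for In Situ Hybridization Probe Panels
Version: 0.1.0
Authors@R:
    person("Panel", "QC Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Predicts off-target binding of padlock-probe gene panels (such as
    10x Genomics Xenium panels) by strict and pad-mode exact alignment of probe
    target sequences to annotated transcriptomes. Reads probe panels from FASTA
    or BED, normalizes GENCODE-, RefSeq- and CHESS-style annotations into a
    uniform transcript set, orients probes onto the transcript forward strand,
    lifts alignment hits to gene-level binding calls with synonym resolution
    and biotype annotation, reconciles predictions across multiple annotations,
    and quantifies the expression-level impact of predicted off-targets via
    CPM/log1p normalization, aggregation, RMSE against the identity line and
    Pearson correlation. Includes a seeded synthetic-data generator that plants
    every supported off-target scenario with a machine-readable truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
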