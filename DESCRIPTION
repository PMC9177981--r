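Package: synergyseq
Title: Hormone Crosstalk and Assisted-Loading Analysis of Expression and
    Binding Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrative analysis of two-hormone crosstalk from four-condition
    (untreated, each single hormone, dual) sequencing experiments.
    Provides a negative-binomial Wald test for differential expression and
    differential ChIP binding, classification of synergistically induced and
    antagonized genes, classification of assisted versus unassisted
    transcription-factor binding sites, position-weight-matrix log-odds motif
    scanning with threshold relaxation, enhancer-cluster detection with
    cluster-level motif co-occurrence and signal quantification, and a
    ground-truthed synthetic-data generator that plants interaction classes,
    motifs and condition-dependent coverage so that every stage of the
    pipeline can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
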