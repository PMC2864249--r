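Package: mirnaome
Title: Small RNA Profiling and Plant miRNA Discovery from Two-Condition
    Sequencing Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for comparative plant miRNAome analysis
    from small RNA sequencing of two conditions (e.g. a wild type and a
    mutant): anchored adapter trimming, collapsing of reads into unique
    signatures with per-library counts, hierarchical classification against
    non-coding RNA, transcript and mature miRNA catalogues, novel miRNA
    discovery by stem-loop (hairpin) folding with sequenced miRNA* duplex
    evidence, TPM normalisation with a two-proportion Z test for differential
    abundance, plant-style miRNA target complementarity scoring, and
    miRNA-target small RNA hotspot statistics. A synthetic-data generator
    with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: SmallRNA, Sequencing, DifferentialExpression, GenePrediction
RoxygenNote: 7.3.3
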