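Package: peakCobind
Title: Integrative ChIP-Seq Co-Occupancy, Motif and Cross-Species
    Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating transcription-factor ChIP-seq peak sets
    with gene annotation and expression data. Assigns peaks to genes by
    proximity to transcription start sites, classifies genes by
    co-occupancy of two factors (common versus uncommon binding), scans
    peak sequences with JASPAR position frequency matrices using log-odds
    relative scores, projects foreign-species bound gene sets onto a
    reference species through ortholog maps to measure conservation of
    regulatory targets, and tests association between binding classes and
    differentially expressed gene sets with contingency-table statistics.
    Includes a synthetic-data generator with recorded ground truth so the
    whole pipeline is testable without external downloads, and a
    config-driven end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'annotation.R'
    'association.R'
    'peaks.R'
    'cooccupancy.R'
    'cross_species.R'
    'motif.R'
    'pipeline.R'
    'simulate.R'
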