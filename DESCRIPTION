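Package: epimark
Title: Island-Based Differential Histone-Mark and Factorial Expression
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for characterizing histone
    methyltransferase mutants from ChIP-seq and expression microarray
    data. Implements window-cluster calling of broad histone-mark
    islands against input chromatin, differential island detection
    between genotypes or treatments, gene-body metagene profiling with
    scaled-body bins and fixed flanks, replicate concordance checks and
    ChIP-qPCR percent-input summaries, per-gene three-way factorial
    ANOVA of a genotype x carbon x light design with Benjamini-Hochberg
    control, and hypergeometric gene-set integration (direct and
    functional targets, responsiveness partitions,
    expression-methylation binning, chromosomal cluster scans). A
    synthetic-data generator with per-gene ground truth emulates the
    study design at desk scale so every stage can be validated by
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
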