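Package: meripqc
Title: Quality Assessment of MeRIP-Seq and m6A-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-guided quality assessment of methylated RNA
    immunoprecipitation sequencing (MeRIP-seq / m6A-seq) experiments.
    From aligned IP and Input BAM files and a GTF annotation, the package
    computes read-distribution statistics over genomic regions, exonic
    coverage-class histograms, quantile metagene profiles, exome signal
    extraction scaling (ESES) immunoprecipitation-efficiency metrics,
    exact conditional Poisson-mean (C-test) enrichment profiles,
    size-factor normalized multi-sample comparisons (hierarchical
    clustering, PCA, mean-SD heterogeneity, replicate consistency), and
    renders a self-contained HTML quality report with verdicts against
    published good-quality reference ranges. A synthetic-data module
    generates toy transcriptomes and BAM files with planted stop-codon
    proximal enrichment and artifact modes for testing.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    base64enc,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
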