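Package: duetSeq
Title: Parent-of-Origin Transcriptome Analysis of Mixed Two-Accession RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate maternal and paternal transcripts in bulk RNA-seq
    of mixed male+female plant tissue using SNPs between two accessions. Builds
    variant-substituted diploid transcript references from a reference genome,
    gene models and filtered SNP calls; assigns read fragments to parental
    transcripts with an EM estimator under a Bayesian (Dirichlet) prior so that
    reads without any SNP are shared between the two genomes; normalizes
    abundances to tissue-proportion-corrected nFPKM; classifies genes as
    expressed, sex-preferential or sex-specific; selects pollination-induced
    gene sets by fold change and adjusted p-value with Venn set algebra; and
    predicts sex-specificity for SNP-less genes from the labels of their
    top-ranked co-expression neighbors (Expression Correlation Method). A
    synthetic-data module generates two-accession genomes, mixed-tissue
    paired-end reads and co-expression rank tables with recorded ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
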