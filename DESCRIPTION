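Package: cdscan
Title: Pooled-DNA GWAS Allelotyping and HLA Tag-SNP Risk Models for Coeliac Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the computational chain of a coeliac-disease (CD)
    genetic-risk study as a tested, simulation-backed pipeline: calling
    HLA-DQ2.5/DQ2.2/DQ8 diplotypes from four HLA-tagging SNPs; a pooled-DNA
    allelotyping genome-wide scan built on the relative allele signal (RAS),
    per-chip MAPD quality control, Welch t-tests between case and control
    pools and Benjamini-Hochberg adjustment; individual-genotyping
    case-control statistics (chi-square tests, Wald odds-ratio confidence
    intervals, logistic interaction models under dominant and recessive
    codings); and rule-based CD risk classifiers that combine HLA risk
    diplotypes with the MSH5 variant rs3130484 and the HLA-DQA1-proximal
    variant rs9272346, evaluated by sensitivity and specificity under a
    minimum-specificity constraint. A synthetic-cohort and pooled-array
    simulator with the study's statistical structure makes every stage
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: GenomeWideAssociation, SNP, Genetics, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'cdscan-package.R'
    'gwas.R'
    'hla.R'
    'io.R'
    'risk.R'
    'synthetic.R'
    'utils.R'
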