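Package: riskloci
Title: Integrative Regulatory Annotation of GWAS Risk Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links GWAS risk loci to regulatory chromatin through a tested,
    seed-deterministic pipeline: linkage-disequilibrium (r^2 >= 0.2) proxy
    regions around sentinel SNPs, chromatin-state enrichment against a
    merged background-region model, genotype reconciliation of imputed and
    whole-genome-sequencing calls, multi-layer molecular QTL scanning
    (chromatin accessibility, H3K27ac, DNA methylation, expression),
    beta-binomial allelic-imbalance testing, and position-weight-matrix
    allele-disruption scoring.  A synthetic-data generator emulates every
    data layer so the full pipeline runs and is testable without access to
    controlled genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
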