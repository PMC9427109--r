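Package: sgscan
Title: Population Genomics of a Balanced Supergene Polymorphism
Version: 0.1.0
Authors@R:
    person("sgscan", "developers", email = "sgscan@example.org", role = c("aut", "cre"))
Description: Tools for analysing a balanced two-arrangement supergene system of
    the kind found on white-throated sparrow chromosome 2 (ZAL2/ZAL2m):
    identification of arrangement-diagnostic fixed differences from
    morph-labelled genotypes, chromosome-of-origin assignment of sequencing
    fragments and construction of arrangement-resolved pseudo-haplotypes,
    coverage-corrected windowed diversity and divergence statistics (pi, dXY,
    df, FST, Tajima's D), site-frequency spectra, coding-sequence piN/piS,
    linkage-disequilibrium decay, H-statistic sweep scans with SNP-binned
    empirical p-values, a kernel beta statistic for balancing selection,
    Patterson's D, outlier-region detection with haplogroup clustering, and
    integration of allele-specific expression with selection scans. Includes a
    forward Wright-Fisher simulator of a balanced inversion polymorphism with
    disassortative mating so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
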