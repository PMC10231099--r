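Package: beeIntrogress
Title: Colony-Level Introgression Analysis for Polyandrous Honey Bees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating C-lineage introgression into Apis mellifera
    mellifera colonies from pooled and individual sequencing data. Implements
    pooled allele-frequency estimation from AD/DP read counts, frequency-based
    ABBA BABA statistics (Patterson's D, the f admixture-proportion estimator,
    and the f4-ratio) with equal-SNP-count block jackknife significance, a
    combinatorial reference-trio test battery, and a maximum-likelihood
    admixture model with supervised mode and cross-validation. A synthetic
    haplodiploid colony simulator generates lineage allele-frequency panels,
    polyandrous colonies with mixed patrilines, pooled read counts, and
    single-worker genotypes with the statistical structure the analysis
    assumes, and writes them as VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Sequencing, Coverage, Genetics
RoxygenNote: 7.3.3
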