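Package: linepanel
Title: Genomic Analysis of Iso-Female Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of quantitative trait variation in
    panels of iso-female inbred lines of haplodiploid insects. Includes a
    pedigree-explicit simulator of inbred line panels with realistic linkage
    disequilibrium and residual heterozygosity, genotype and phenotype input
    with the standard line-panel filtering rules, pooled window diversity
    statistics (nucleotide diversity, Watterson's theta, Tajima's D), pairwise
    line F_ST and population-structure checks, hyperbolic linkage
    disequilibrium decay fitting, broad-sense heritability from brood-level
    data, single-marker mixed-model association scans with permutation-based
    empirical significance thresholds, windowed cross-trait rank-overlap tests
    for shared genetic architecture, and a lightweight variant-effect
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    lme4,
    vcfR,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
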