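Package: depthconcord
Title: Depth Titration of Whole-Genome Variant Calling Accuracy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates how sequencing depth drives small-variant calling
    accuracy. Simulates a diploid truth catalog of SNVs and indels with a
    configurable alternate-allele-frequency spectrum, a microarray-like
    truth subset with genotyping QC metadata, and depth-dependent call sets
    with Poisson site coverage, allele dropout, and GATK-style INFO
    annotations. Applies hard-filter criteria, builds 3x3 genotype
    concordance matrices against the truth panel, and computes concordance
    rate, false positive/negative rates, non-reference true positive rate,
    Ts/Tv ratios, allele-frequency-stratified accuracy, indel concordance
    against an all-reads reference, and four-digit HLA genotyping accuracy,
    across a seeded depth-titration sweep with replicate averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
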