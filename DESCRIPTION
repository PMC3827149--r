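Package: poolgwas
Title: Two-Stage DNA-Pooling Genome-Wide Association Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pooling-based genome-wide association studies in a
    case-control design. Estimates group allele frequencies from two-channel
    pooled-array intensities with per-SNP dye-bias correction (heterozygote
    correction factor k, relative allele signal, homozygote normalization,
    replicate-variance quality control), screens SNPs with gender-stratified
    chi-square tests, Benjamini-Hochberg false discovery rate control and a
    rank-sum combination across genders, and analyses individually genotyped
    SNPs (Hardy-Weinberg equilibrium, allele and Cochran-Armitage trend
    tests, per-allele and per-genotype odds ratios with Woolf confidence
    intervals, non-central chi-square power). Includes a synthetic-data
    generator that emulates gender-stratified case/control pools assayed in
    triplicate, and an end-to-end pipeline with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
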