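Package: sweepscan
Title: Selection Scans and Genotype-Phenotype Association for Population Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for detecting recent positive selection from
    phased population genomic data and testing candidate variants for
    phenotype associations. Implements per-site Weir-Cockerham FST and the
    population branch statistic (PBS), haplotype-length scan statistics
    (nSL and XP-nSL) with frequency-bin normalization, a composite test
    that merges derived-allele-frequency-binned empirical p-values with
    the harmonic mean p-value, and covariate-adjusted additive/dominant
    linear-model association testing. Ships forward Wright-Fisher and
    Balding-Nichols simulators so every stage can be validated on
    synthetic haplotype and phenotype data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
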