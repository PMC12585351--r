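Package: diffAD
Title: Differential Allelic Dispersion from Population-Scale RNA-seq Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects population-level allele-specific dysregulation from bulk
    RNA-seq allele counts without genotyping data. Per-SNP three-component
    beta-binomial genotype mixtures are fit by expectation-maximization, with
    cohort-level sequencing-error and inbreeding metaparameters estimated from
    a fast binomial mixture. Differential allelic dispersion (dAD) between a
    control and a case cohort is tested per SNP by a likelihood-ratio test and
    by a score test that reuses the null fit across sample-label permutations.
    SNP-level P values are aggregated to genes with a dependence-corrected
    weighted Lancaster method whose covariance correction is estimated by
    shared-label permutations, and a "canonical dAD" statistic correlates each
    case sample's allelic extremity with its expression. A synthetic-data
    generator reproduces the full generative structure (Hardy-Weinberg
    genotypes with inbreeding, sequencing error, group-specific heterozygote
    overdispersion) for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
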