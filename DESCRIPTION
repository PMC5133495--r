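Package: famkat
Title: Family-Based Kernel Association Tests for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate- and kinship-adjusted variance-component (kernel) score
    tests of SNP sets on quantitative traits in pedigrees. Fits the polygenic
    null model by restricted maximum likelihood with a pedigree kinship
    covariance, computes linear and radial-basis-function kernels with
    minor-allele-frequency based SNP weights, obtains p-values for the
    quadratic-form score statistic by Davies' method, and provides three
    strategies for jointly testing rare and common variants: a single combined
    kernel, a trace-weighted sum of the rare and common statistics, and
    Fisher pooling of correlated p-values. Includes a gene-drop pedigree
    simulator with LD-structured haplotypes for calibration and power studies,
    and readers for VCF dosages, PED pedigrees, BED regions and phenotype
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    vcfR,
    withr,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
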