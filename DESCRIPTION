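Package: exposomeMR
Title: Exposome-Wide Two-Sample Mendelian Randomization Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for exposome-wide two-sample Mendelian randomization
    screens against a binary outcome such as survival to extreme old age.
    Provides S4 containers for GWAS summary statistics, instrument selection
    with LD clumping and strength diagnostics (F-statistic, power),
    exposure-outcome allele harmonization including palindromic-SNP
    resolution by allele frequency, causal-effect estimators
    (inverse-variance weighted, MR-Egger, weighted median, multivariable MR),
    MR-PRESSO global and outlier tests, FDR-tiered screening with
    concordance checks and validation-stage merging, and a synthetic-data
    generator with known ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'estimators.R'
    'exposomeMR-package.R'
    'harmonize.R'
    'instruments.R'
    'presso.R'
    'utils.R'
    'sumstats.R'
    'screen.R'
    'simulate.R'
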