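Package: rfiflock
Title: Residual Feed Intake Phenotypes, Repeatability and Mixed-Model GWAS
    for Two-Period Sheep Feeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives residual feed intake (RFI) and related growth
    phenotypes (average daily gain, mid-test body weight, metabolic body
    weight, dry-matter intake) from longitudinal weight and feed-intake
    records collected over two physiological periods (growth and
    maintenance), quantifies trait correlations and between-period
    repeatability by REML with a parametric bootstrap, and runs an
    EMMAX-style mixed-model genome-wide association scan with a VanRaden
    genomic relationship matrix fitted as a random effect. A synthetic
    flock generator with two-breed Balding-Nichols genotype structure, a
    polygenic RFI component and a causal variant supplies ground truth for
    every stage. Readers and writers for PLINK text and binary genotype
    files and for the trial's delimited phenotype tables are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
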