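Package: gnurture
Title: Genetic-Nurture Decomposition of Polygenic and Socioeconomic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how offspring genome and parental
    socioeconomic status (SES) jointly shape a cognitive phenotype in
    sibling-clustered longitudinal cohorts. Provides polygenic scoring
    from GWAS weight files (PLINK raw dosages, allele reflection,
    within-stratum standardization), ancestry principal components, SES
    design construction with explicit missing-category coding, a
    neighborhood-disadvantage index and SES summary principal component,
    three-level random-intercept models with likelihood-ratio tests,
    gene-environment interaction fits, sibling fixed-effects checks, a
    Falconer twin descriptive, and an incremental R-squared decomposition
    that corrects SES and PGS estimates for parental-genome ("genetic
    nurture") confounding. A trio-based cohort simulator with Mendelian
    transmission and transmitted/non-transmitted score bookkeeping
    supports validation by parameter recovery against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    lme4,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
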