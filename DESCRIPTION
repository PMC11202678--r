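Package: phsgp
Title: Genomic Prediction of Pre-Harvest Sprouting Resistance in Winter Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of pre-harvest sprouting (PHS)
    resistance in winter wheat breeding populations. Provides genotype
    quality control and minor-allele recoding, the VanRaden genomic
    relationship matrix, germination index computation, REML estimation of
    repeatability and heritability from unreplicated augmented designs,
    GBLUP genomic prediction with optional QTL-marker fixed-effect
    covariates, stratified cross-validation of predictive ability,
    across-season prediction scenarios, two-marker haplotype analysis of a
    major dormancy locus, and a synthetic breeding-population generator
    that emulates the multi-environment trial structure the analysis
    assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
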