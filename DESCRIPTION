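Package: aimselect
Title: Ancestry-Informative Marker Selection and Panel Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores the ancestry informativeness of biallelic markers across
    two or more populations from allele-frequency data alone, using a
    mean-square-contingency (Lancaster) estimator of independence on the
    Hardy-Weinberg-expected genotype-by-population table. Also ranks markers
    from individual-level genotypes (estimated-frequency LEI, PCA loadings,
    linear-SVM coefficients, random-forest importance), builds thinned AIM
    panels by score threshold and physical spacing, simulates ancestral and
    admixed cohorts under a Balding-Nichols divergence model, and validates
    panels by supervised ancestry-proportion estimation (RMSE against truth)
    and principal-component separation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    cluster,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'admixture.R'
    'aimselect-package.R'
    'io.R'
    'lei.R'
    'panel.R'
    'ranking.R'
    'simulate.R'
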