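Package: bufgen
Title: Quantitative Genetics of Body Size and Ultrasound Carcass Traits in
    Yearling Buffalo
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based quantitative-genetic analysis pipeline for
    yearling water-buffalo growth and in-vivo ultrasound carcass traits.
    Builds the numerator relationship matrix from pedigree records,
    standardizes repeated field measurements to a 365-day age by linear
    interpolation or extrapolation, fits fixed-effect least-squares models
    with Tukey multiple comparisons and produces fixed-effect-adjusted
    phenotypes, estimates additive and maternal genetic variance components
    by EM-REML under the univariate animal model and predicts breeding
    values (BLUP), derives direct, maternal and total heritabilities,
    EBV-based genetic correlations, phenotypic correlations, and direct and
    relative correlated responses to selection, and tests candidate-SNP
    genotype effects on adjusted phenotypes by one-way ANOVA.  A synthetic
    herd generator with the same additive + maternal covariance structure
    supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    emmeans,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
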