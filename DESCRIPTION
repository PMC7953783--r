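Package: nirherit
Title: Genetic Parameters for NIR-Predicted Meat Quality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage quantitative-genetic analysis of at-line near-infrared
    (NIR) spectral predictions of beef quality traits. Stage one fits Bayes B
    chemometric calibrations of laboratory-measured traits (colour, pH, water
    losses, shear force) on standardized absorbance spectra and evaluates them
    by leave-one-batch-out external validation. Stage two estimates pedigree
    animal-model (co)variance components by bivariate AI-REML, with random
    herd, slaughter-batch, additive-genetic and residual effects, yielding
    intra-herd heritabilities of measured and predicted traits and the genetic
    and residual correlations between them. A synthetic-data generator with a
    configurable pedigree, variance partition and spectral information content
    makes every stage testable end to end, and an evaluation module derives
    variance-loss statistics and indirect-selection efficiencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
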