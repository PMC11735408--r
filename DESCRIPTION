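Package: exomet
Title: Rare-Variant Burden Testing of Metabolite Levels and In Silico
    Knockout Flux Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A coupled metabolomics-exome analysis toolkit: qualifying-variant
    masks and gene-based burden tests of rare-variant effects on metabolite
    levels (with X-chromosome hemizygote dosage coding and sex-stratified
    effect comparison), forward selection of driver variants, metabolite
    matrix preprocessing (probabilistic quotient normalization, rank-based
    inverse normal transformation, effective number of tests), in silico
    gene-knockout flux modeling on stoichiometric metabolic models via
    linear and minimum-norm quadratic programming ("virtual inborn errors
    of metabolism"), fixed-effect panel estimation of knockout effects
    across personalized model ensembles, and clinical readout statistics
    (Firth penalized logistic regression, exact contingency tests, allelic
    series correlations, age- and sex-specific z scores). Includes a
    synthetic-data module that generates annotated cohorts, metabolite
    matrices and analytically solvable toy metabolic networks with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
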