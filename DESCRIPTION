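Package: seedless
Title: Quantitative Analysis of Seed-Independent microRNA Target Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for classifying and quantifying microRNA target sites that
    pair to the miRNA 3' region without seed complementarity. Implements a
    target-site grammar with offset arithmetic over 3' and seed segments,
    maximum-likelihood relative-Kd inference from AGO RNA bind-n-seq
    concentration series, a multiplicative decomposition of compound-site
    affinities, equilibrium and pseudo-first-order kinetic curve fitting with
    nearest-neighbor free-energy comparison, chemical-probing reactivity
    quantification, an occupancy-based repression model for massively
    parallel reporter assays with slicing detection, a 3' UTR targetome
    survey, cohort-based expression-response testing, and synthetic-data
    generators with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'binding-kinetics.R'
    'compound-model.R'
    'expression.R'
    'site-grammar.R'
    'mpra.R'
    'probing.R'
    'rbns-kd.R'
    'survey.R'
    'synthetic-data.R'
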