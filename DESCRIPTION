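Package: episparrow
Title: Multi-Objective Sparrow Search for Higher-Order Epistasis Detection in Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects second- and higher-order epistatic interactions in
    case-control genome-wide association data with a multi-objective sparrow
    search algorithm. Candidate SNP combinations are scored with three
    contingency-table objectives (Bayesian K2, conditional entropy and Gini
    impurity, each with a table-length truncation that removes the bias toward
    long genotype tables), aggregated by rank sum, and refined by a K2-guided
    backward noise elimination; surviving combinations are gated by a G-test of
    independence and a p-value ratio filter that trims weak tail findings.
    Includes a penetrance-model simulator in the GAMETES tabular dialect
    (Hardy-Weinberg sampling, heritability-targeted search for models without
    marginal effects) and a benchmark harness reporting recall, precision,
    F-measure and power against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
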