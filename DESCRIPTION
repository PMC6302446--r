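Package: comboscreen
Title: Drug-Pair Combination Screen Scoring and Deep Response Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling tumor cell line response to drug pair
    combination screens. Aggregates dosed growth-fraction measurements to
    per-tuple minimum-growth targets (MinComboGrowth), computes a best-dose
    combination score (BestComboScore) against a modified multiplicative
    expectation, preprocesses cell-line omics and drug descriptor matrices,
    and fits a two-level residual feedforward network with a weight-shared
    symmetric drug encoder to predict growth from molecular and chemical
    features. Includes stratified cross-validation, a random-pair baseline,
    error-aggregation views, top-K virtual-screening rankings, and a seeded
    synthetic screen generator with planted synergistic pairs for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
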