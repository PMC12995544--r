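Package: htesens
Title: Sensitivity Analysis for Heterogeneous Treatment Effects in Matched
    Observational Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how unmeasured confounding affects inference
    about heterogeneous treatment effects in matched observational studies
    under Rosenbaum's Gamma sensitivity model. Provides optimal pair and
    variable-ratio matching with propensity calipers, almost-exact matching
    and near-fine balance; weighted M-statistics with worst-case null
    moments; CART-based subgroup discovery with rematching and truncated
    product closed testing (the HSR procedure); the submax and submax+
    maximum-deviate procedures with closed testing over correlated normal
    deviates; amplification of the sensitivity parameter to interpretable
    (Lambda, Delta) pairs; and a simulation framework measuring statistical
    power and effect-modifier identification by F1 score and true positive
    rate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    mvtnorm,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
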