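Package: paguard
Title: Counterfactual Assessment of Protected-Area Effects on Species Range Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying terrestrial species range contraction and
    local extinction on an equal-area grid and for estimating the causal
    effect of protected areas (PAs) on those losses. Implements gridded
    range-change accounting (lost, retained, gained), species richness and
    local extinction-rate maps, classification of pixels into protection
    time frames (protected since the past reference year, protected later,
    buffer, never protected), propensity-score matching with standardized
    mean difference balance diagnostics, gradient-boosted multilevel
    treatment-effect estimation with partial dependence, and species- and
    landscape-level regressions of range loss on protection coverage. A
    seeded synthetic-world generator produces confounded landscapes with
    known treatment effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
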