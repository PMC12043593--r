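Package: lesionmsa
Title: Iterative Multi-Perturbation Shapley Value Analysis for Lesion Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate lesion-symptom inference by iterative estimated
    Multi-perturbation Shapley value Analysis (MSA). From graded region-of-interest
    lesion loads and binary behavioural outcomes, the package trains a random-forest
    surrogate that predicts performance from lesion configurations, estimates each
    region's game-theoretic (Shapley) contribution by permutation sampling with
    bootstrap uncertainty, and iteratively discards weak contributors into a
    "rest of brain" element until the smallest region set with a non-significant
    rest-of-brain contribution is found. Includes exact Shapley enumeration for
    small games, lesion-load extraction from labelled volumes, lesion-pattern
    correlation, and a synthetic cohort generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
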