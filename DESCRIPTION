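Package: pfnet
Title: Bayesian Constraint-Based Causal Discovery for Psychopathology Scale
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a general psychopathology factor (the
    p-factor) shapes the network structure of clinical scale scores. The
    package provides a synthetic bifactor/hierarchical generator for
    dichotomous item pools organised into nine restructured-clinical-style
    scales and six spectra, one-factor maximum-likelihood factor analysis and
    p-factor proxy scale extraction, and a Bayesian constraint-based causal
    discovery engine (BGe model averaging over small variable subsets with a
    Bayes-factor fallback, reliability-ordered skeleton construction,
    FCI-style orientation, and exogeneity constraints for context variables
    in the spirit of joint causal inference). A study pipeline compares five
    model configurations, counts cross-spectrum links, tracks their
    resolution when a p-factor proxy is added, and classifies the resulting
    attachment pattern as bifactor-like or hierarchical.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
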