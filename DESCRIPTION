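Package: tempomon
Title: Temporal Genetic Monitoring of Supplemented Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for long-term genetic monitoring of small, supplemented
    populations: per-sample diversity statistics with rarefaction and
    resampling-based sample-size correction, Hardy-Weinberg and linkage
    disequilibrium quality control, Weir-Cockerham F-statistics and
    three-level AMOVA with permutation tests, four effective-population-size
    estimators (temporal moments, unbiased Fs, pseudo-maximum-likelihood,
    and single-sample linkage disequilibrium) with their bias corrections
    and infinity semantics, demography/environment/supplementation
    association tests, and a forward Wright-Fisher simulator with hatchery
    supplementation and known per-generation truth for estimator validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
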