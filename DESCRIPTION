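Package: redoxscreen
Title: Analysis Pipeline for RNAi Oxidative-Stress Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end computational analysis of genome-wide RNAi
    oxidative-stress viability screens: per-siRNA effect-size statistics
    (Cohen's d with 95 percent confidence intervals and five-bin
    classification), reduction of BLAST tabular hits to a target-gene catalog,
    construction of protein-protein interaction networks with
    first/second-shell expansion and largest-connected-component analysis,
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction and kappa-score term clustering, and drug-target cross-database
    mining for repurposing candidates. Includes a synthetic-data generator
    that emulates every input with planted ground truth so the whole pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
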