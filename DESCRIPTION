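Package: sddp
Title: Predicting Susceptibility Degree to a Disease from Literature-Mined Pathway Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating an individual's degree of future susceptibility
    to a disease from literature-derived molecular evidence. The pipeline mines
    marker-disease associations from abstracts with strict clause-level linguistic
    rules and a co-occurrence z-score filter, transforms a molecular interaction
    network into per-marker shortest-path characteristic trees, links pathways into
    a hierarchy network through their shared molecules, infers undetected deficient
    pathways by propositional forward chaining with replayable proof traces, and
    converts an individual's pathway combination into a risk indicator via
    Copeland-style pairwise dominance ranking over per-publication co-occurrence
    weights. Includes seed-reproducible synthetic corpus and network generators
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
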