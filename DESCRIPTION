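Package: pathnet
Title: Pathway Model Integration and Active Subnetwork Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates curated pathway models into a single unified network in
    which every biochemical interaction is reified as its own node with edges
    to all participant molecules (gene products, metabolites, complexes).
    Differential-expression statistics are overlaid as node attributes and
    score-optimal active subnetworks are discovered by aggregating
    z-transformed p-values with Monte-Carlo background calibration and a
    depth-limited greedy search. Also provides gene-set overrepresentation
    analysis with a hypergeometric Z-score and label-permutation p-values, and
    a synthetic-data generator with planted signal so the whole pipeline can
    be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
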