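Package: chemnet
Title: Chemical-Genetic Screen Scoring and Seed-Gene Network Inference
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns humanized-yeast chemical-genetic and synthetic genetic
    array (SGA) screen data into ranked mechanisms. Provides growth-curve
    and endpoint statistics (mid-log residual growth, four-parameter
    log-logistic IC50, drug-drug synergy ratios, Phloxine B viability,
    sterol fractions), plate normalization and two-stage hit calling for
    epistasis and chemical-genomic screens, per-cell fluorescence scoring
    of protein abundance and localization changes, seed-gene network
    inference on a confidence-filtered interactome (first-order and
    Steiner minimum networks, betweenness centrality, map-equation
    community detection with degree-preserving significance testing),
    hypergeometric over-representation analysis with Benjamini-Hochberg
    control, and a deterministic synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
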