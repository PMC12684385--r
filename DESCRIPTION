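Package: oncopanels
Title: Individualized Cancer Driver Panels from Mutations, Expression and
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies short, individualized driver-gene panels (iPanels)
    for cancer patients by integrating somatic mutation calls, per-sample
    expression fold changes and a directed protein-protein interaction
    network. Patient networks are contextualized with expression-derived
    node and edge weights, least-cost shortest paths from mutated genes are
    mined (Mutpaths), driver panels are extracted by greedy maximum set
    cover over reachable differentially expressed genes, a prognosis risk
    score (PiRS) is computed from Cox hazard ratios and network scores,
    per-patient panels are aggregated into cohort-level Condorcet rankings
    benchmarked against gold-standard driver lists, and panel genes are
    mapped to drugs through a rule-based actionability matrix. A synthetic
    cohort generator with planted ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
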