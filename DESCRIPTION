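Package: cigsurvey
Title: Conditional-Independence Graphs for Mixed-Type Health-Survey Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs functioning and context sum indices from health-survey
    item batteries, estimates a conditional-independence graph over mixed
    discrete and continuous variables with graphical random forests (per-node
    random-forest models scored by symmetrized permutation importance) under
    stability selection with an upper bound on the expected number of falsely
    selected edges, and interrogates the estimated graph for structural claims
    (isolated nodes, separate components, adjacency, separation, and pathways
    between impairment and activity-and-participation limitation). Includes a
    synthetic-cohort generator with a known ground-truth dependence structure,
    calibrated to published marginal distributions of the 2007 Swiss Health
    Survey, for recovery and error-control simulations.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
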