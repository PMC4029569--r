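Package: edmsnet
Title: Differential Co-Expression Network Modules by Edgewise Dense Module Search
Version: 0.1.0
Authors@R:
    person("edmsnet", "developers", email = "edmsnet@example.org", role = c("aut", "cre"))
Description: Identifies condition-specific protein interaction modules from
    multi-stage gene expression data by differential co-expression. For every
    interactome edge, stage-wise Pearson correlations are Fisher-transformed and
    differenced across consecutive stages to give a dC statistic; top-ranked
    differentially co-expressed pairs seed a greedy edgewise dense module search
    (eDMS) guarded by a relative module-score decrease tolerance delta, with
    delta chosen by a grid scan of the overall module score. Transition-wise
    subnetworks are summarised (hubs, recurrent edges, stage-pattern labels),
    unioned and clustered by dC trajectory (complete-linkage hierarchical
    clustering), and annotated by hypergeometric gene-set enrichment with
    Benjamini-Hochberg adjustment. Includes a seeded synthetic data generator
    that plants edge groups with prescribed per-stage correlation trajectories
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
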