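Package: vitnet
Title: Vitamin-Informed Microbial Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds compositional co-occurrence networks from genome-resolved
    relative-abundance tables using SparCC-style basis correlations, overlays
    per-genome vitamin-biosynthesis capability calls derived from KEGG ortholog
    annotations, and scores vitamin-producing genomes with a vitamin-hubness
    metric together with a label-randomization null distribution, in order to
    nominate organisms likely to provision B vitamins to correlated auxotrophs.
    Includes network topology summaries (betweenness centrality, density,
    Louvain and Girvan-Newman modules), condition-stratified ecology
    comparisons, and a synthetic-community generator with planted correlation
    modules and a planted provisioning hub for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'correlation.R'
    'ecology.R'
    'hubness.R'
    'io.R'
    'network.R'
    'pathways.R'
    'pipeline.R'
    'simulate.R'
    'vitnet-package.R'
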