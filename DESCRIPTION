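Package: flavornet
Title: Co-Expression Network Analysis of Fruit Ripening Transcriptomes and
    Flavor Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for small multi-stage fruit ripening RNA-Seq
    designs (three stages by three replicates). Implements the exact
    Poisson-based two-library differential expression test with
    Benjamini-Hochberg screening, FPKM normalization and four-group
    expression-profile classification, an unsigned weighted gene
    co-expression network (soft-threshold adjacency, topological overlap,
    average-linkage module detection, eigengenes, module merging),
    module-trait and gene-trait Pearson association against flavor
    metabolite concentrations, intramodular hub selection, Cytoscape edge
    export, and delta-delta-Ct qPCR quantification. Ships a seeded
    synthetic-data generator with planted co-expression modules and
    linearly coupled trait vectors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
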