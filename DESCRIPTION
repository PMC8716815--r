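Package: endopersist
Title: Seasonal Dynamics and Persistence of Host-Associated Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-season microbiome count tables:
    abundance-table preprocessing (low-abundance filtering, rarefaction),
    Hill-number diversity with sample-size-based rarefaction and extrapolation,
    Bray-Curtis dissimilarity with NMDS ordination and permutation tests
    (PERMANOVA, ANOSIM), the Sloan neutral community model with per-taxon
    deviation classification and cross-season deviation persistence, the
    Raup-Crick null-model index of assembly stochasticity, and per-season
    Spearman co-occurrence networks combined into a season-persistence network
    with graph-level property summaries. Includes a synthetic multi-season
    community generator (neutral Dirichlet-multinomial backbone with planted
    non-neutral taxa and planted season-persistent correlated pairs) so every
    stage can be exercised and validated without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
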