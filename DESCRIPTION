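Package: wetnet
Title: Temporal Dynamics and Co-Occurrence Networks of Wetland Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the temporal dynamics and co-occurrence
    structure of soil microbial communities from OTU count tables: rarefaction,
    alpha and beta diversity (Bray-Curtis, unweighted UniFrac), principal
    coordinate analysis, seeded permutation tests (PERMANOVA, ANOSIM, Mantel),
    time-decay regression of community similarity, Spearman co-occurrence
    network construction with random-matrix-theory threshold selection, Zi-Pi
    node-role classification, keystone identification, and network robustness
    under random or targeted species loss. Includes a synthetic OTU-table
    generator with planted correlation modules and treatment-dependent
    temporal drift for end-to-end validation, and a pipeline driver that
    reproduces the full analysis per site-by-treatment group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
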