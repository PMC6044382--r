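Package: degnet
Title: Directed Gene Networks and Hub Genes from Perturbation Signature Databases
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs directed upstream-to-downstream regulatory networks
    among user-supplied differentially expressed genes (DEGs) by matching the
    query signature against a reference database of genetic-perturbation
    expression profiles (knockdown, overexpression, ligand treatment), using a
    Kolmogorov-Smirnov connectivity score, ROC-based cutoff selection with
    Youden's J statistic, direction-consistency and off-target filters, and
    weighted Kleinberg hub/authority scoring to rank DEGs by their influence
    on the network. Includes a synthetic reference-database generator with
    planted regulatory hierarchies so the full pipeline can be exercised
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
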