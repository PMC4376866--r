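Package: pocketpath
Title: Network-Based Drug-Target Interaction Prediction over Bipartite
    Ligand/Binding-Site Similarity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-docking style target identification: ligands and
    protein binding sites form the two partitions of a weighted bipartite
    network in which similarity edges (chemical similarity between
    compounds, structural similarity between pockets) stay within a
    partition and experimentally observed ligand-site interactions cross
    it.  Query compounds are linked into the network by a random-forest
    compound-pair classifier, candidate targets are ranked by
    distance-bounded shortest paths (score = inverse summed path
    distance), standardized into global and per-target local Z-scores,
    and classified as binder/non-binder by a random-forest
    meta-classifier.  Includes redundancy condensation of each
    sub-network (maximal-clique cover or k-core collapse with
    maximum-weight cluster edges), integration filters for modeled
    binding sites, a full benchmark protocol (positive/negative set
    construction, miss-annotation screening, identity-edge exclusion,
    ROC/AUC, precision/recall, enrichment), and a seeded synthetic
    universe generator so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    igraph,
    ranger,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
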