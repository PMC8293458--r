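Package: litcooc
Title: Bioconcept Co-Occurrence Networks from Annotated Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mining entity-annotated biomedical literature:
    reading and writing the PubTator annotation exchange format and
    MEDLINE citation exports, publication-trend and MeSH-keyword
    scientometrics, exclusive (UpSet-style) set-intersection profiles
    over PMID membership matrices, and weighted co-occurrence knowledge
    graphs (document-bioconcept bipartite, bioconcept-bioconcept, and
    class-induced subgraphs such as gene-gene) with centrality,
    modularity and top-node summaries. Includes a seeded synthetic
    corpus generator with ground-truth bookkeeping so every stage of
    the pipeline is testable without live database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    patchwork,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
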