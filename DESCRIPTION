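Package: regnda
Title: Meta-Curation and Natural Decomposition of Bacterial Regulatory
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble bacterial transcriptional regulatory
    network models from heterogeneous curated edge lists and to dissect
    their functional architecture.  Gene symbols are disambiguated
    against a locus-tag dictionary by a constrained bipartite mapping;
    independent datasets are merged into meta-curated models with
    evidence-aware reconciliation of effects; global network statistics
    include robust (Huber) power-law fits of degree and clustering
    distributions.  The natural decomposition approach derives a
    network-specific connectivity threshold (the kappa value) from the
    clustering-versus-out-degree curve and classifies every gene as a
    global regulator, modular gene, basal-machinery gene or intermodular
    gene; modules are functionally annotated by hypergeometric GO
    enrichment with false-discovery-rate control.  Seeded generators of
    planted benchmark networks, identity dictionaries and annotations
    make the whole pipeline testable without external data.
License: MIT + file LICENSE
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
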