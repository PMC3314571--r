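Package: orthosignal
Title: Detecting the Orthology Signal in Protein-Protein Interaction
    Networks at the Functional-Complex Level
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how much of the functional-complex structure of a
    protein-protein interaction (PPI) network is attributable to orthology
    rather than to global topology or chance.  The whole network, the
    subnetwork induced by an ortholog protein set, and many subnetworks
    induced by random protein samples are each clustered with the Markov
    Cluster algorithm; clusters are turned into putative complexes by
    Gene Ontology enrichment (one-sided Fisher's exact test, Bonferroni
    corrected) under a three-criterion functional-coherence rule; a
    per-function retrieval index compares the classes, and functions whose
    retrieval in the ortholog class strictly exceeds both the global class
    and the 95th percentile of the random null are reported as
    orthology-related, together with the complexes that carry them,
    unique/verified/novel function predictions, and GO-slim summaries.
    Includes parsers for edge-list, OBO 1.2 and GAF 2.x formats and a
    synthetic fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
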