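Package: spreadrank
Title: Multi-Attribute Ranking of Influential Spreaders in Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and ranks influential spreader nodes in undirected
    networks by combining several local and semi-local structural indices
    (degree, k-shell, neighbourhood coreness, mixed degree decomposition,
    k-shell iteration factor, H-index, hierarchical k-shell, an entropy-based
    ranking measure, and a gravity index) through a simplified ELECTRE
    outranking procedure with Shannon-entropy criterion weights. Ground-truth
    spreading power is estimated by Monte-Carlo simulation of the
    susceptible-infected-recovered (SIR) epidemic model, and rankings are
    evaluated with Kendall rank correlation, top-c Jaccard similarity and a
    monotonicity statistic. Ships the Zachary karate-club network and its
    published node-by-criterion decision matrix as plain-text fixtures.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
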