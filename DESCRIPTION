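Package: smirn
Title: Simplified Memory Information Retrieval Network Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a bi-modular hierarchical memory network in which words
    are memorized as paths in a rooted letter trie, retrieval strengthens the
    network by re-parenting retrieved nodes and their former ancestors directly
    to the root (path compression), and unused words decay through a virtual
    node that climbs from the treetop to the root. Provides the intra-modular
    trie engine, an inter-modular region graph (ring, complete, or custom
    topology) with first-letter word assignment, an instrumented merge-find set
    (union by size with path compression) as the efficiency baseline, average
    search length experiments, standard complex-network statistics (average
    path length, clustering coefficient, degree distribution), a seeded Zipf
    corpus generator, and a reproducible experiment runner with JSON/TSV/CSV
    artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
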