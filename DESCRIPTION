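Package: probnetalign
Title: Global Alignment of Uncertain Biological Networks
Version: 0.1.0
Authors@R:
    person("Jordan", "Carver", email = "jcarver.dev@fastmail.com",
           role = c("aut", "cre"))
Description: Global pairwise alignment of protein-protein interaction
    networks whose edges carry existence probabilities. Builds the expected
    IsoRank-style support matrix of two uncertain networks using probability
    generating functions of node degrees, solves for a node-pair similarity
    vector by power iteration blended with normalized sequence similarity,
    and extracts a one-to-one alignment by maximum-weight bipartite
    matching. Deterministic and half-probabilistic alignment are recovered
    as special cases (all edge probabilities equal to one). Includes
    possible-worlds enumeration oracles, a synthetic-network generator with
    planted alignments, alignment quality metrics (agreement, GO
    consistency, global network alignment score), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
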