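Package: fibnet
Title: Fibration Symmetries, Input Trees and Building Blocks of Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fibration symmetries in directed multigraphs such as
    enzyme-enzyme metabolic networks: minimal balanced coloring identifies
    fibers (groups of nodes with isomorphic input trees), which are collapsed
    into the quotient base graph. Input-tree layer sequences and their
    limiting branching ratios characterize each fiber's building block, which
    is classified into fiber-number classes |n,l>, simple and composite
    (feed-forward / feedback) Fibonacci structures and multi-layer stacks.
    Includes construction of enzyme networks from reaction tables with
    currency-metabolite filtering, node-role decomposition into strongly
    connected components, connectors and the k_out shell, and benchmarking of
    fiber partitions against network motifs (Z-scores under a
    degree-preserving null model) and directed-modularity modules (adjusted
    Rand index).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
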