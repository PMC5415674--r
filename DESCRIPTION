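Package: nefsim
Title: Dataflow Simulation and Operator-Merging Graph Optimization for
    NEF-Style Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A miniature dataflow backend for spiking neural networks in the
    style of the Neural Engineering Framework (NEF). Models are collections of
    named memory blocks (signals, with zero-copy views) and typed operators
    declaring set/increment/read/update access, from which a dependency graph
    and a topologically sorted execution schedule are derived. The package
    implements a computation-graph optimizer that fuses identical operators
    and re-lays their operands into contiguous memory blocks -- turning many
    small dense matrix-vector products into one block-sparse product --
    while provably preserving step-by-step simulation semantics. Includes a
    spiking leaky integrate-and-fire engine, exact direct-mode execution,
    synthetic network generators (circular-convolution binding networks,
    split-ensemble models, random models and DAGs), an interned
    transitive-closure reachability structure, JSON model serialization, and
    a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
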