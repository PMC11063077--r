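Package: crnsteer
Title: Operator-Steered Exploration of Chemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale framework for operator-guided, reproducible,
    automated exploration of chemical reaction networks (CRNs).
    Explorations alternate Selection and Network Expansion steps over a
    persistent store of structures, compounds, flasks, elementary steps
    and reactions.  Reaction discovery uses single-ended forced scans
    with bond-order-change detection and transition-state-guess
    selection, a fast dissociation screen with barrierless-step probing,
    and molecular-graph isomorphism de-duplication.  A deterministic
    pairwise-Morse surrogate calculator makes every component runnable
    in seconds; an adapter slot is left for real electronic-structure
    engines.  Includes an energetically-lowest-path search on the
    bipartite compound/reaction graph with level-diagram export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
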