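Package: ktgel
Title: Grasshopper-Pruned Extreme Learning Machines for Force-Myography
    Gesture Recognition
Version: 0.1.0
Authors@R:
    person("FMG", "Tools", email = "fmg.tools@example.org", role = c("aut", "cre"))
Description: Extreme learning machines (ELM) whose randomly initialized
    input-weight matrix is pruned by a binary grasshopper optimization
    algorithm with k-tournament selection. Connection-level pruning yields
    simultaneous hidden-node reduction and implicit feature selection
    (the KTGEL classifier). Includes a wrapper feature selector with the
    ELM as evaluation classifier, window-level statistical feature
    extraction for multi-channel force-myography (FMG) signals, a seeded
    synthetic FMG generator with controllable subject variability and
    class ambiguity, micro-averaged multiclass evaluation, and a
    command-line workbench reproducing the full experimental loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
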