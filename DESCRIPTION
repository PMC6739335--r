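Package: brcnet
Title: Boundary-Reaching Control of Synchronous Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for controlling synchronous Boolean network models of
    molecular regulatory systems by one-time temporary perturbation.
    Identifies the exact basin of attraction of a desired attractor by a
    hierarchical backward search that exploits structural network
    reductions (iterative peeling of outdegree-0 "symmetric" nodes and a
    deterministic/nondeterministic node partition), represents large basins
    compactly as disjoint wildcard cubes with exact counts, and finds all
    minimum control target sets that drive an undesired state onto the
    basin boundary (boundary-reaching control). Also provides Monte-Carlo
    attractor-landscape estimation, persistent-clamping fixation-cascade
    simulation with interruption experiments, and control-target
    probability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
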