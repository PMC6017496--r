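Package: basinselect
Title: Basin-Based Decoy Selection on Sampled Protein Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Organizes template-free protein structure prediction decoys into
    basins of the sampled energy landscape via an epsilon-nearest-neighbor
    graph and discrete negative-gradient descent, characterizes basins by
    size, focal energy, pseudo-saddles, persistence and stability, and ranks
    them for decoy selection by size, size-then-energy, or Pareto
    rank/count on the (size, -energy) objectives. Includes the
    follow-the-leader clustering and uniform-random baselines, native-fraction
    and purity evaluation metrics over top-x group unions, a synthetic
    planted-landscape generator for testing, and plotting/reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    ggplot2,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
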