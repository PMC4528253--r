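Package: ptmfp
Title: Function-Potential Ranking of Post-Translational Modification Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters experimentally observed post-translational modifications
    (PTMs) onto multiple-sequence-alignment columns ("hotspots"), projects the
    hotspots onto family-representative 3D structures, and ranks each hotspot
    by a Function Potential (FP) score that combines observation count,
    solvent accessibility (Shrake-Rupley), protein-interface residence, and
    residue conservation. Includes separation statistics for hotspots with
    known versus unknown function, a synthetic-fixture generator with planted
    signal for end-to-end validation, and an orchestration layer with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    Biostrings,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
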