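Package: karyofuse
Title: Alignment-Free Recognition of Chromosome Fusion Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects chromosome fusion events (e.g. Robertsonian
    translocations) between two sets of chromosome-scale sequences without
    alignment or annotation. Whole chromosomes are embedded as k-mer natural
    vectors (per-k-mer counts, mean positions and scaled second central
    moments); fused-chromosome vectors are derived algebraically from the
    vectors of their segments, every candidate fusion scenario is scored by a
    normalized two-part distance (cosine dissimilarity of vectors plus length
    difference) under an optimal bipartite assignment, and the minimum-loss
    scenario is reported together with the full chromosome correspondence.
    Includes a synthetic-rearrangement simulator with planted ground truth,
    multidimensional-scaling visualisation of chromosome distances, vector
    caching, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
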