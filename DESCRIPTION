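Package: fragscape
Title: Morphological Spatial Pattern Analysis and Fragmentation Statistics
    for Binary Habitat Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fragmentation of a focal land-cover class
    (e.g. farmland) in categorical rasters. Segments binary landscapes into
    the seven morphological spatial pattern analysis (MSPA) classes (core,
    islet, bridge, loop, perforation, edge, branch) at pixel level; computes
    class-level landscape pattern indices (patch density, normalized
    landscape shape index, patch cohesion, effective mesh size) and the
    landscape contagion index; estimates discrete-time Markov chains over
    class maps from two dates, with convergence-rate and normalized-entropy
    diagnostics; and provides change-rate, correlation and accuracy/kappa
    statistics for area time series. Includes a modified-random-clusters
    neutral landscape generator and deterministic geometric fixtures with
    analytically known MSPA classes, plus an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
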