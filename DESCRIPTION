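Package: netlesion
Title: Lesion Analysis of Resting-State Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds group-level binary brain graphs from multi-subject
    regional time series (Pearson correlation, Fisher r-to-z, edgewise
    one-sample t-tests, Bonferroni-Holm familywise-error thresholding) and
    quantifies network robustness via Latora-Marchiori global efficiency
    and information centrality under simulated lesioning of single nodes,
    target networks (e.g. the default mode network), edge sets, and whole
    hemispheres.  Includes a synthetic generator of modular, band-limited
    regional signals with planted community and hub structure for two age
    groups, so that every pipeline stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
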