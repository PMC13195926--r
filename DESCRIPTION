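Package: treetarget
Title: Tree-Based Consensus Localization of Personalized Brain-Stimulation Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Locates personalized, near-scalp, connectivity-guided targets for
    transcranial magnetic stimulation (TMS) in volumetric brain data. Implements
    a tree-based consensus algorithm that sweeps sulcal-depth (or
    distance-to-scalp) and seed functional-connectivity thresholds, extracts
    connected-component centroids into trees of candidate targets, and selects
    the consensus candidate closest on average to all others. Also provides the
    connectome-guided cluster and cone baseline algorithms, an evaluation
    suite (scalp proximity, test-retest reliability ratios, inter-session seed
    connectivity, linear distance-to-intensity conversion, electric-field
    hotspot metrics), and a synthetic phantom-head generator so the entire
    pipeline can be exercised without any MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
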