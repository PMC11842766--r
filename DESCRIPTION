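Package: foodnet
Title: Representational Similarity Networks for Food-Responsive Brain Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for partitioning food-responsive brain regions
    into representational sub-networks and relating their multivariate geometry
    to behaviourally derived food-similarity structure. Implements odd-one-out
    triplet similarity estimation, correlation-distance representational
    dissimilarity matrices (RDMs), RDM-of-RDMs network clustering with
    silhouette validation and outlier screening, permutation-based
    representational similarity analysis (RSA) with network-level group tests,
    spherical searchlight RSA mapping, and amplitude-modulated GLM analysis of
    rating tasks. A synthetic-data module generates every input with planted
    ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
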