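Package: sagakit
Title: Quantification of 3D Spheroid Collective Invasion, Chain Tracking,
    and Permutation-Based Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for image-guided studies of collective cancer
    invasion. Quantifies 3D spheroid invasion from time-lapse image stacks
    (standard-deviation z-projection, Gaussian smoothing, graph-cut binary
    segmentation, morphological polishing, and per-frame invasion features
    including invasive radius, invasive area, skeleton-endpoint branch counts
    and circularity); computes invasive-chain track metrics (path length,
    displacement, velocity, pre/post leader-detachment splits); and implements
    a paired-difference permutation test for differential expression on a
    four-group leader/follower/photoconverted-control design that screens out
    photoconversion artifacts. Ships synthetic-data generators (spheroid
    phantoms with analytic ground truth, persistent-random-walk chain tracks,
    and expression matrices with planted effects) so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    limma,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
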