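Package: bicopam
Title: Consensus Clustering of Gene Expression Across Multiple Datasets
    with Tunable Binarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers consistently co-expressed gene modules across many
    expression datasets with the Bi-CoPaM ensemble scheme: each dataset is
    clustered independently by k-means with Kaufman initialisation, a
    bubble-neighbourhood self-organising map, and Ward hierarchical
    clustering; partitions are relabelled by greedy min-min matching and
    fused into a fuzzy consensus partition matrix (CoPaM) whose memberships
    are pushed towards binary values; the final CoPaM is binarized by the
    difference threshold technique over a sweep of the tightness parameter
    delta.  Clusters are scored by a per-gene mean squared error averaged
    over datasets, ranked by tightness, and screened for anti-phase
    (negatively correlated, zero-lag) cluster pairs.  A synthetic
    multi-dataset generator with planted anti-phase modules supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
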