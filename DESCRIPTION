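Package: ghdiff
Title: Differential Sub-Network Detection with the Generalized Hamming Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical comparison of two undirected networks defined on a
    shared node set. Implements the Generalized Hamming Distance (GHD) between
    mean-centered connectivity weights, closed-form mean and variance of its
    permutation null together with normal-approximation p-values, and a
    per-node decomposition of the centralized GHD. On top of the statistic it
    provides three iterative differential sub-network detection algorithms
    (Closed-Form, Fast Approximation, and a dGHD baseline driven by the change
    in centralized GHD), cosine-similarity and one-step topological-overlap
    connectivity weights, random geometric and static power-law benchmark
    generators with planted differential sub-networks, and evaluation tools
    (confusion metrics, Cohen's kappa, ROC/PR curves and AUCs, multi-run
    benchmark tables, theta-sensitivity profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
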