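Package: dynGRN
Title: Dynamic Gene Regulatory Network Inference from Multi-Omic
    Differentiation Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step inference of stage-specific gene regulatory networks
    during cellular differentiation. A logistic regression model learns a
    per-base transcription factor occupancy probability (the LR score) from
    sequence conservation, gene structure, nearby-gene expression and
    histone-modification ChIP-seq features. The LR scores, position weight
    matrix hits, temporal expression profiles and perturbation data are then
    combined in a time-varying dynamic Bayesian network whose per-gene convex
    objective (sparse cis-segment weights with fused-L1 smoothing of edge
    weights across adjacent stage transitions) is solved by ADMM, yielding
    stage-resolved regulator-target networks, the cis-segments that mediate
    them, bootstrap significance for segment weights, and in-silico
    transcription factor perturbation predictions. A synthetic-data module
    generates complete toy datasets (planted motifs, enhancer-like signal
    bumps with binding-site dips, expression trajectories from a known
    network) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
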