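Package: tripfall
Title: Trip-Related Fall-Risk Prediction from Gait Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling trip-related fall risk in older adults from
    regular-walking kinematics. Computes 40 spatiotemporal and sagittal-plane
    angular gait features (centre-of-mass state, margin of stability, joint and
    trunk angles, step geometry and timing) from 3D marker trajectories over one
    gait cycle, ranks features with multiclass ReliefF, trains bagged
    decision-tree ensembles over 20 nested feature subsets built by
    importance-based backward elimination, and evaluates them with repeated
    stratified cross-validation, one-vs-rest ROC/AUC, and accuracies at the
    default and Youden-optimal cutoffs. A synthetic-data module generates
    class-conditional feature tables and marker-level gait trials with known
    ground truth, so the full pipeline is testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
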