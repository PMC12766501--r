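Package: odtgclust
Title: Outcome-Guided Deep Temporal Graph Clustering of Multi-Organ
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subphenotypes critically ill patients from multi-organ
    trajectory data with an outcome-guided deep temporal graph clustering
    network: per-patient sequences of attributed organ-interaction graphs
    are encoded by a recurrent, attention-fused graph/variational encoder
    and clustered with a self-supervised student's-t soft assignment.
    Includes a synthetic cohort generator with planted trajectory
    archetypes, the preprocessing pipeline (binning, missingness filters,
    IQR outlier censoring, fill imputation, normalization), organ-state
    coupling analytics via embedding cosine similarity, model selection
    by the elbow rule with silhouette and Davies-Bouldin diagnostics, an
    early gradient-boosted phenotype classifier, Kaplan-Meier survival
    stratification, and a stabilized inverse-probability-weighted
    analysis of heterogeneous fluid-strategy treatment effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    nnet,
    survival,
    sandwich,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
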