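Package: neurodep
Title: Discovery of Depression Subnetworks from Heterogeneous Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis chain for relating intracranial EEG
    network structure to depression status across subjects with
    heterogeneous electrode coverage. Builds subject-level and population
    correlational models of whole-brain field-potential activity with
    radial-basis-function imputation, reconstructs signals at unsampled
    locations by Gaussian-process (kriging) regression, parcellates the
    population network into functional modules by modularity maximization
    with allegiance and hub analysis, extracts Morlet band-power
    spectral-spatial features, classifies depression status with
    leave-one-out cross-validated PCA plus L1-regularized logistic
    regression and a permutation null, decomposes the classifier into
    network expression patterns by hierarchical biclustering of log-odds
    impacts, and contrasts module-pair connectivity between groups with
    Cohen's d and permutation significance. Includes a synthetic-cohort
    generator with planted ground truth so every stage is testable without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    glmnet,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
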