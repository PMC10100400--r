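Package: simsMetab
Title: Untargeted Metabolomics for Secondary-Ion Mass Spectrometry Depth Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for untargeted metabolomics from
    high-mass-resolution secondary-ion mass spectrometry (OrbiSIMS) depth
    profiles of tissue regions. Provides ppm-window feature alignment of
    per-site peak lists into a SummarizedExperiment-backed feature matrix,
    missing-value filtering and k-nearest-neighbour imputation, total-ion-count
    normalization and Pareto scaling, principal component analysis and an
    orthogonal projections to latent structures discriminant analysis
    (OPLS-DA) engine with VIP scores, S-plot coordinates, leave-one-out Q2 and
    permutation validation, univariate testing with false-discovery-rate
    control, adduct-aware accurate-mass annotation against a bundled compound
    table, metabolic pathway coverage mapping, single-ion image construction
    with region-of-interest statistics, and a synthetic depth-profile cohort
    generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: Metabolomics, MassSpectrometry, Software, DifferentialExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
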