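Package: hemiconn
Title: Hemispheric Brain Network Construction, Metrics and Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs functional and structural hemispheric brain networks
    from per-subject whole-brain weighted connectivity matrices (Pearson
    correlations from resting-state fMRI, streamline counts from diffusion
    imaging), quantifies intra- and inter-hemispheric connectivity, weighted
    global and local efficiency with degree-preserving random-network
    normalization, intra- and inter-hemispheric nodal degree, and
    functional-structural coupling, and runs the full two-way mixed
    group-by-hemisphere ANCOVA inferential design with post hoc tests,
    Bonferroni-corrected region-wise statistics, partial brain-clinical
    correlations and density-grid (AUC) plus regional-size validation
    analyses. Includes a seeded synthetic cohort generator with planted
    group effects, hemispheric asymmetry, homotopic enhancement and
    controllable cross-modal coupling for ground-truth testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
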