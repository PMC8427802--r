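Package: exomarker
Title: Trajectory-Based Marker Discovery for Neuron-Derived Exosome Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discovering candidate protein markers of
    cognitive decline from quantitative proteomics of neuron-derived exosomes.
    Takes a log2 protein expression matrix over three cognitive stages
    (normal, mild cognitive impairment, Alzheimer's disease) and performs
    fuzzy c-means soft clustering of stage trajectories, detection of
    monotone bridge clusters, hypergeometric over-representation analysis
    with Benjamini-Hochberg adjustment and core/pivotal pathway logic,
    pairwise differential expression on log2 fold changes, key-protein
    intersection, protein-protein interaction network centralities, and
    four-parameter logistic ELISA calibration with CD81 normalization.
    Includes a seeded synthetic-cohort generator with planted trajectory,
    annotation, network and plate structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
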