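Package: epiconn
Title: Episodic Memory Quality and Cortico-Hippocampal Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for continuous-report episodic memory
    experiments with simultaneous fMRI. Fits von Mises + uniform mixture
    models to circular response errors, derives posterior-probability
    success thresholds, quantifies feature-binding dependency and a
    composite 0-3 memory-quality score, estimates HRF-weighted background
    functional connectivity with Louvain modularity and network-density
    metrics, and fits memory-modulated generalized psychophysiological
    interaction (gPPI) models. Includes a synthetic-data generator that
    emulates the behavioural and BOLD structure of a color/scene/emotion
    object-association paradigm so every stage can be validated against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
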