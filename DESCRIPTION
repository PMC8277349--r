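Package: pfcensembles
Title: Neuronal Ensemble Analysis for Prefrontal Calcium Imaging During
    Pavlovian Reward Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium imaging of cortical
    populations recorded during head-fixed Pavlovian reward conditioning.
    Provides lick-based behavioural scoring (normalized auROC cue
    discrimination), trial-aligned peristimulus time histograms, spectral
    clustering of trial-response vectors with silhouette-based
    hyperparameter selection into neuronal ensembles, ensemble-resolved
    binary decoding of task variables against permutation nulls, and
    longitudinal stability analyses of cells tracked across sessions.
    Includes a calcium-transient simulator that generates complete
    synthetic conditioning sessions with planted ensemble structure for
    validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    cluster,
    e1071,
    mclust,
    data.table,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
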