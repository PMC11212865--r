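Package: tepmap
Title: Community Detection and Stimulus-Response Mapping for Dense TMS-EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dense transcranial magnetic stimulation
    EEG (TMS-EEG) stimulus-response mapping. Builds TMS-evoked potential
    (TEP) connectivity and similarity matrices from the stimulation-condition
    and recording-channel perspectives, detects communities with a
    signed-modularity Louvain algorithm and agreement-matrix consensus,
    quantifies coil-orientation sensitivity by community agreement and by
    permutation-null modularity, summarizes electric-field-thresholded
    stimulation regions of interest against a 100-parcel 7-network atlas,
    and compares the summaries across communities with covariate-adjusted
    nonparametric statistics. A synthetic-data generator with planted
    community structure makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
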