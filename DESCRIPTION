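Package: captrans
Title: Temporal Transition Analysis of Co-Activation Patterns in Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the temporal organization of characteristic
    resting-state functional-connectivity (RSFC) patterns in fMRI time
    series. Each fMRI frame is matched to its best-fitting reference
    pattern by spatial correlation, pattern-to-pattern transitions are
    counted into a directed transition matrix, transitions are tested
    against a permutation null on run-length-consolidated label
    sequences with FDR control, and the resulting weighted directed
    transition network is characterized by community structure
    (consensus Louvain) and hub scores. Includes minimal temporal
    preprocessing (framewise-displacement scrubbing, nuisance
    regression, band-pass filtering), head-motion control analyses, and
    a synthetic-data generator with a planted Markov transition
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    lme4,
    signal,
    RNifti,
    jsonlite,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
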