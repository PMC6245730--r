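Package: preictal
Title: Preictal and Ictal Electrophysiology Analysis of Spike Trains, LFP,
    and Optogenetic Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing extracellular
    recordings collected around chemoconvulsant-induced seizures: z-score
    detection of ictal onset from the local field potential (LFP),
    partitioning of the recording into baseline, preictal quartiles and
    15-second ictal sub-periods, waveform-based classification of
    regular-spiking cells, optogenetic tagging of interneurons,
    firing-rate and temporal-patterning statistics (local variation,
    inter-spike-interval burst ratio), spike-field coherence via pairwise
    phase consistency, sigmoid input-output characterisation of
    light-evoked spiking, pulse-triggered suppression indices, and
    nonparametric group statistics with Bonferroni correction. A
    synthetic-session generator with known ground truth stands in for raw
    tetrode recordings so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
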