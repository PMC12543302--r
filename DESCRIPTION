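Package: gammanet
Title: Gamma-Band EEG Functional Network Topology, Wiring Cost, and
    Ictogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for gamma-band electrophysiological
    functional networks in rodent skull-surface EEG. Estimates debiased
    weighted phase-lag index (dwPLI) connectomes from multichannel
    recordings, characterizes network topology (Onnela clustering,
    small-world propensity against equivalent regular and random null
    models, betweenness and eigenvector centrality, normalized weighted
    rich-club curves), quantifies spatial wiring cost with a normalized
    total effective wiring cost (TEWC) based on the rearrangement
    inequality together with segregative and integrative cost-efficiency,
    simulates seizure propensity of connectome-coupled theta-neuron
    networks (brain network ictogenicity and node ictogenicity), extracts
    auditory evoked potential N1 components, and provides permutation-based
    factorial statistics. Includes a synthetic-data generator producing
    electrode layouts, phase-coupled recordings, and factorial cohorts with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
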