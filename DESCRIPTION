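Package: mapkflow
Title: Steady-State Signal-Flow Modeling of Stress MAPK Driver Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Phenomenological steady-state network-flow model of the stress
    MAP kinase (MAPK) driver network that controls BACH1 transcription in
    triple-negative breast cancer cells. Represents kinase signaling
    topologies (including the crosstalk-containing N1 and crosstalk-free N2
    benchmark networks) as conserved flow graphs, propagates a normalized
    stress signal to predict relative BACH1 output under single-drug and
    low-dose four-drug (4D-MAPKi) inhibition, accounts for the per-kinase
    signal surplus created by treatment, and decides compensatory-network
    activation against a configurable threshold. Includes calibration of
    dose-response constants from tabular readouts, a synthetic-data
    generator for random conserved topologies and noisy replicate
    dose-response measurements, and tidy tabular outputs with ggplot2
    visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
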