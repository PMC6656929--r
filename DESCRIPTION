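Package: angionet
Title: Rule-Based Simulation of the Extracellular Tumor Angiogenesis Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compartmental, rule-based model of the extracellular network of
    pro-angiogenic (VEGF, FGF2) and anti-angiogenic (TSP1, PF4) factors in tumor
    tissue, including their receptors, cell-surface and interstitial heparan
    sulfate proteoglycan pools, and matrix metalloproteinase-driven proteolysis.
    Provides a site-graph rule engine that expands seed species and reaction
    rules into a concrete mass-action reaction network, a stiff ODE simulator
    with steady-state detection and depot (controlled-release) sources, and the
    standard in-silico experiments for this model family: baseline distribution
    profiling, angiogenic-ratio secretion scans, cHSPG x PF4 response grids,
    Monte Carlo secretion sampling, and pulsed PF4 release protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
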