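Package: hicforge
Title: Simulation and Statistics for Hi-C Chromosome Organization
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators for the large-scale features of nuclear organization that
    Hi-C contact maps capture: A/B compartment eigenvectors and saddle-plot
    compartmentalization strength, contact-frequency distance decay P(s) and its
    log-log derivative, chromosome territoriality (cis fraction), diamond-window
    insulation scores with TAD boundary calling and boundary-set algebra,
    telomere/centromere clustering statistics, scaled inter-chromosomal maps,
    virtual 4C profiles and a mitochondrial-nuclear contact score. A parametric
    generator of synthetic genome-wide contact maps (power-law distance decay,
    two-state compartment blocks, planted insulating boundaries, tunable cis
    share, chromosome-end clustering, mitochondrial leak) provides presets
    emulating a fibroblast to iPSC to maturing motor-neuron trajectory so every
    estimator is verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
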