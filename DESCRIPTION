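Package: epidrift
Title: Multiscale Stochastic Simulation of Epigenetic Stem-Cell Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-cell simulation of epigenetic drift in stem cell
    populations. Couples transcription driven by an artificial-genome
    transcription-factor network, bistable H3K4me3 dynamics on cooperative
    nucleosomes with recruitment feedback, replication-coupled DNA
    methylation gated by the histone state, and a two-compartment
    niche/proliferation population model with age-related phenotypes and
    clonal competition. Provides exact master-equation analysis of the
    histone-modification chain, scenario presets for aging phenotypes
    (reduced differentiation, reduced proliferation, altered niche
    affinity), tidy trajectory outputs, gene-class and clone-census
    observables, and sensitivity sweeps over the histone methyltransferase
    rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
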