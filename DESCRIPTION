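Package: cosolve
Title: Co-Solvency Modelling and Green-Solvent Screening for Drug-Like Solutes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the solubility of drug-like solutes in neat
    and binary aqueous-organic solvents and for screening environmentally
    friendly dissolution media. Implements the Buchowski-Ksiazczak (lambda-h)
    and Jouyban-Acree co-solvency models with a two-pass outlier-curation
    procedure, sigma-profile algebra and a sigma-potential solver in the
    COSMO-RS spirit with hydrogen-bonding, hydrophobicity and interaction-
    energy descriptors, an iterative saturation-solubility estimator anchored
    on fusion properties, an ensemble of single-hidden-layer neural networks
    with explicit accuracy/precision/reliability admission gates and an
    applicability-domain check, and a screening driver that filters candidate
    solvents by environmental index and re-expresses ensemble predictions as
    Jouyban-Acree parameters. Synthetic generators for sigma-profiles,
    solubility datasets and descriptor tables make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    withr,
    jsonlite,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
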