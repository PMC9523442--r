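Package: lungmech
Title: Premature Lung Tissue Mechanics and Epithelial Sodium Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of uniaxial tension and compression tests on soft lung
    tissue and of Ussing-chamber electrophysiology of distal lung epithelial
    monolayers. Implements the van der Waals (Kilian) hyperelastic network
    model for stress-strain curves, Young's modulus estimation by linear
    regression of the small-strain regime and by full-range hyperelastic
    fitting, the ventilation-physiology derivation of experimental
    deformation velocities, short-circuit-current and inhibitor-response
    quantification of transepithelial sodium transport, and the
    normality/variance-homogeneity decision tree for group comparisons.
    Includes seeded synthetic-data generators that emulate both experiment
    families so every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
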