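Package: asdkit
Title: Drug-Polymer Solubility and Miscibility Modeling for Amorphous Solid Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for screening and modeling drug-polymer solubility and
    miscibility in amorphous solid dispersion (ASD) formulation. Implements
    group-contribution solubility parameters (Fedors, Hoftyzer-van Krevelen,
    Just-Breitkreutz) with Bagley distances, Flory-Huggins melting-point-
    depression analysis with chi(T) fitting and binodal/spinodal construction,
    a PC-SAFT equation-of-state engine for solid-liquid and liquid-liquid
    equilibria with binary interaction parameter fitting, the Kyeremateng
    empirical solubility equation, Gordon-Taylor and Kwei glass-transition
    mixing rules, and assembly of annotated temperature-composition phase
    diagrams. Includes seeded synthetic-data generators for melting-point-
    depression and glass-transition datasets so every fitting stage has
    parameter-recovery tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
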