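Package: lipochrom
Title: Chromatographic Lipophilicity Indices and In Silico ADME Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines chromatographic lipophilicity indices for drug
    candidates from reversed-phase chromatography: log kw from RP-HPLC
    retention factors and RM0 from RP-TLC retardation factors, both by
    linear extrapolation of retention against the organic-modifier volume
    fraction (the Soczewinski-Wachtmeister model), together with the
    isohydric modifier fraction phi0. Includes concordance analysis of the
    experimental indices against seven calculated logP scales, Lipinski
    lipophilicity screening, rule-based classification of pkCSM-style ADME
    descriptors, a synthetic chromatography data generator with
    parameter-recovery studies, and a bundled dataset of 28
    2-aminothiazol-4(5H)-one derivatives.
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
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
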