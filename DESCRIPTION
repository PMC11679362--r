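Package: terminomeR
Title: Peptidome and Terminome Analysis of Thermal Proteolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize endogenous proteolysis from label-free
    peptidomics data, motivated by sous-vide cooking of fish muscle. Maps
    quantified free peptides onto a parent proteome, reconstructs cleavage
    events at peptide termini, and summarizes protease cleavage-site
    specificity as Schechter-Berger P2-P2' subsite matrices per cooking
    condition, with condition contrasts and per-protein degradation
    quantification. Includes a stochastic in-silico proteolysis simulator
    with known ground truth for validating every pipeline stage, and
    texture profile analysis (TPA) curve parameterization with Dunnett
    many-to-one comparisons against a raw control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    mvtnorm,
    rlang,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
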