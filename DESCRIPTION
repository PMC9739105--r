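Package: mtxkit
Title: Quantitative Analysis of a Microtubule-Targeting Venom Peptide
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for characterizing crotamine-family venom
    peptides (myotoxin-3) as microtubule-targeting agents. Provides
    disulfide-aware peptide mass arithmetic and MALDI in-source-decay c/z
    fragment-ladder annotation; segmentation of microtubule length-history
    tracks into growth, shortening and pause phases with the full dynamic
    instability statistic set (rates, length changes, time fractions,
    catastrophe and rescue frequencies, dynamicity) and condition
    comparisons; turbidimetric tubulin-polymerization curve metrics (lag,
    plateau, maximal rate); and a Wiseman one-set-of-sites isothermal
    titration calorimetry model with nonlinear fitting and derived
    thermodynamics. A seeded synthetic-data module generates stochastic
    three-state dynamic-instability trajectories, sigmoidal turbidity
    curves, one-site ITC isotherms and fragment spectra with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
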