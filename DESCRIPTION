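Package: coexwas
Title: Co-Expression-Wide Association Studies with Genetically Regulated
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains genetic imputation models for pairs of molecular
    exposures (gene or protein expression) and for their genetically
    regulated co-expression, then jointly tests direct and interaction
    effects on a complex trait.  Stage one fits penalized linear models
    (elastic net, lasso or ridge) on pre-screened cis- or genome-wide
    xQTLs; stage two estimates the three trait effects either from
    individual-level data or from GWAS summary statistics combined with a
    linkage-disequilibrium reference panel.  Includes variant quality
    control, rank-based inverse-normal phenotype adjustment, marginal
    QTL mapping with sure independence screening, a standard PWAS
    baseline, and a synthetic-data generator with known pQTL, coQTL and
    outcome architecture for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
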