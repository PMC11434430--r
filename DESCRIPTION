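Package: tlclipo
Title: Chromatographic Lipophilicity from RP-TLC Retention Data with QSPR
    and Chemometric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines chromatographic lipophilicity (logP_TLC) from
    reversed-phase thin-layer chromatography retardation factors: converts
    R_F to R_M, fits the linear Soczewinski-Wachtmeister retention model
    R_M = R_M0 + b*C per compound, extrapolates to zero organic modifier,
    calibrates R_M0 against reference standards with literature logP, and
    predicts logP_TLC for unknowns. Includes QSPR helpers (descriptor
    correlation matrices, simple-regression summaries with full inferential
    statistics, descriptor-activity correlations), chemometric analyses
    (single-linkage hierarchical clustering on Euclidean distances with
    Newick export, principal component analysis with scree summaries), a
    seeded synthetic-plate and descriptor-table generator for validation,
    packaged fixtures of published retention and descriptor tables, CSV and
    JSON input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
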