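Package: qsarmlr
Title: GA-MLR QSAR Modelling with Full Validation, Applicability Domain and
    Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates multi-linear QSAR models of the kind used
    in ligand-based drug discovery. Computes a family of topological and
    geometric molecular descriptors from 3D structures (bond-distance pair
    counts, centre-of-mass shell counts, and the ratio of molecular to
    solvent-accessible surface area), selects descriptor subsets by a
    genetic algorithm with leave-one-out Q2 fitness under the QUIK
    collinearity rule, and validates fitted models with the standard
    internal, cross-validated, external and Y-scrambling statistic
    batteries (Q2-F1/F2/F3, Lin's concordance correlation, Golbraikh-Tropsha
    and r2m metrics). Leverage-based applicability-domain analysis (Williams
    plot) and library virtual screening with a published arginase-I pIC50
    equation are included, together with synthetic molecule and
    descriptor-matrix generators for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    ChemmineR,
    jsonlite
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
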