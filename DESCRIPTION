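Package: mixqsar
Title: Mixture QSAR Modeling of Nanoparticle-Heavy-Metal Cytotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    modeling of the cytotoxicity of binary mixtures of a nanomaterial with
    heavy-metal compounds. Derives conceptual-DFT electronic descriptors for
    pure components, combines them into mixture descriptors by
    concentration-addition weighting, computes cell viability from plate
    absorbances, partitions components into categories by k-means clustering,
    fits partial least squares, random forest and AdaBoost.R2 regression
    models with two-axis grid search and importance-threshold descriptor
    selection, computes a full internal/external validation battery
    (Q2-LOO, Y-randomization, QF1/QF2/QF3, concordance correlation), and
    performs leverage-based applicability-domain (Williams plot) analysis.
    Includes a synthetic-data generator with known ground truth for
    structure-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    randomForest,
    rpart,
    mixOmics,
    MASS,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
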