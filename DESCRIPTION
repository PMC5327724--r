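Package: selexshape
Title: Quantitative TF-DNA Binding Specificity Models from HT-SELEX with DNA Shape Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives quantitative M-word binding scores from per-round HT-SELEX
    read pools (IUPAC core-motif scanning with a weighted mismatch policy,
    fifth-order Markov background normalization and i-th-root enrichment
    scores), fits L2-regularized linear models of binding specificity on
    k-mer and pentamer-derived DNA shape features (minor groove width,
    propeller twist, roll, helix twist), screens datasets by count, spread
    and regression-consistency quality criteria, localizes shape readout by
    position-wise feature selection (red/blue/combined heat maps and
    per-feature delta R-squared), renders DNA shape and sequence logos,
    compares TF families by principal component analysis, and ships a
    ground-truth HT-SELEX simulator so the whole pipeline is testable on
    synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
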