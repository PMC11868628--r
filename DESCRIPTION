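Package: aigs
Title: Multi-Model Glaucoma Screening from Fundus Images with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a hybrid multi-model glaucoma
    screening network on macula-centered fundus photographs. Provides a
    synthetic fundus phantom generator with analytic ground truth, image
    preprocessing (CLAHE, optic-disc region-of-interest cropping), a family of
    lightweight attention-bottleneck convolutional models (binary classifier,
    U-net segmenter, multi-task model, feedforward fully connected heads)
    with a built-in training engine, optic-disc morphometry (cup-to-disc
    ratios, neuroretinal rim sectors, disc size index, fovea heatmaps),
    decision fusion with adjustable escalation rules, and the evaluation
    statistics used for screening studies (ROC/AUC with bootstrap intervals,
    Youden index, DeLong tests, Bland-Altman agreement, correlation
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
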