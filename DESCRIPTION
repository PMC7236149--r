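Package: altopo
Title: Activity Landscape Construction, Imaging and Topology Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds three-dimensional activity landscapes from compound
    fingerprint and potency data: Tanimoto similarity and singleton
    filtering, 2D embedding by metric multidimensional scaling (SMACOF)
    or a Neuroscale-style radial basis function mapping, Gaussian process
    interpolation of the potency hyper-surface, and potency color coding.
    Derives smooth and rugged reference landscapes by interquartile and
    alternating-septile potency selection, renders multi-view landscape
    images, produces reduced-information image variants (grayscale,
    Otsu black/white, Sobel and Canny edges) and flattened feature
    vectors, and trains convolutional neural network, support vector
    machine and random forest classifiers that distinguish smooth,
    rugged and heterogeneous landscape topologies, with multi-trial
    evaluation (accuracy, weighted F1, Matthews correlation, ROC AUC).
    Includes a synthetic activity-class generator with controllable
    structure-activity-relationship continuity for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    cluster,
    grDevices,
    graphics,
    jsonlite,
    kernlab,
    png,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
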