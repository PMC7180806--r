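Package: ThyroCascade
Title: Coarse-to-Fine Cascade Classification of Thyroid Nodules in
    Ultrasound Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-stage computer-aided diagnosis pipeline for classifying
    thyroid nodules in ultrasound images as benign or malign. The pipeline
    localizes the thyroid region by Otsu binarization and largest-component
    selection, screens easy cases with a frequency-domain power-spectrum
    ratio score under dual calibrated thresholds, and defers ambiguous cases
    to a score-level fusion (MIN/MAX/SUM) of two convolutional network heads
    trained with a class-weighted binary cross-entropy loss. Includes
    patient-level k-fold evaluation, TI-RADS label mapping, and a synthetic
    ultrasound phantom generator so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    jpeg,
    EBImage,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, Preprocessing, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'architectures.R'
    'nnet.R'
    'cnn_fine.R'
    'preprocessing.R'
    'frequency.R'
    'fusion_cascade.R'
    'io_datasets.R'
    'evaluation.R'
    'show-methods.R'
    'synthetic_data.R'
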