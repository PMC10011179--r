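Package: hsidrought
Title: Hyperspectral Identification of Tomato Drought Stress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for grading tomato-plant drought stress
    (well-watered / reduced-watered / deficient-watered) from visible and
    near-infrared hyperspectral leaf images. Covers white/dark reflectance
    calibration of ENVI cubes, leaf ROI segmentation and mean-spectrum
    extraction, genetic-algorithm effective-wavelength selection with an
    SVM cross-validation fitness and restart protocol, ReliefF plus
    Pearson-correlation selection of a weakly correlated reflectance image
    set, LeNet-5 image-feature extraction, spectroscopy-image combination,
    young/mature leaf subsample fusion, and SVM / random-forest /
    one-dimensional DenseNet classifiers with calibration and prediction
    accuracies, per-class precision, recall, F1 and one-vs-rest ROC. A
    bundled leaf-cube simulator reproduces the spectral phenomenology the
    method relies on so the whole pipeline is testable without instrument
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    signal,
    EBImage,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
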