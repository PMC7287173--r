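Package: octskinseg
Title: Segmentation of Epidermis and Hair Follicles in Skin OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-stage segmentation of the epidermis together with
    pilosebaceous (hair-follicle) structures in cross-sectional optical
    coherence tomography images of skin. The first stage is an
    encoder-decoder fully convolutional network with pooling-index
    unpooling and skip concatenation, trained with a Soft-Dice loss under
    patient-wise external cross-validation with internal
    leave-one-fold-out validation and ensemble-averaged prediction. The
    second stage refines the network output by Savitzky-Golay baseline
    estimation of the dermo-epidermal junction, baseline correction,
    morphological area opening of the sub-baseline components, and
    Fourier-descriptor smoothing of each follicular contour. The package
    also provides a synthetic phantom generator for layered, speckled
    OCT-like B-scans with exact ground truth, and the full evaluation
    suite (Dice, Jaccard, follicle counting with relative success rate,
    epidermal thickness with RMSE and MAE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
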