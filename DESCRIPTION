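Package: mibci
Title: Motor-Imagery EEG Decoding with CCA-Wavelet Artifact Removal,
    Regularized CSP and a Hybrid KNN-SVM Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for four-state motor-imagery
    electroencephalography (EEG) decoding. Implements temporal
    preprocessing (50 Hz notch, 8-30 Hz zero-phase Butterworth band-pass),
    blink-artifact removal by canonical correlation analysis across
    hemispheric electrode groups augmented with the vertical
    electrooculogram, combined with VisuShrink wavelet thresholding of the
    first canonical pair (wCCA), regularized common spatial pattern
    (R-CSP) feature extraction with generic learning across subjects, and
    a two-stage classifier that shortlists classes by cosine-distance
    K-nearest neighbours and resolves the shortlist with a pairwise
    support vector machine. Includes a synthetic EEG generator emulating a
    14-channel sensorimotor montage with VEOG blink contamination, an
    evaluation harness (confusion matrices, multi-classifier comparison)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
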