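Package: mrisonify
Title: MRI Slice Sonification and Dual-Stream Image-Audio Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms 2D brain-slice images into audio waveforms via a
    multi-scale multi-orientation Gabor filter bank, a locality-preserving
    Hilbert space-filling-curve time mapping, composite spectrogram assembly
    over a geometric frequency ladder, and Griffin-Lim phase reconstruction.
    Couples the sonified audio with the source images in a dual-stream
    classifier: a lightweight attention-fusion separable-convolution network
    for the image stream, a frozen audio embedder plus random forest for the
    audio stream, and stacked-generalization fusion of out-of-fold stream
    probabilities through a logistic meta-classifier. Includes a two-class
    brain-phantom generator so the whole pipeline runs end to end on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    glmnet,
    randomForest,
    generics,
    png,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti,
    pROC
Config/testthat/edition: 3
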