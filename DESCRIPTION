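Package: mmgdecode
Title: Decoding Finger Movements from Magnetomyographic and Electromyographic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for classifying individual
    finger movements (index and little finger flexions) from simultaneous
    multichannel magnetomyography (MMG, optically pumped magnetometers) and
    surface electromyography (EMG) recordings. Provides a synthetic paired
    MMG/EMG session generator with known ground-truth channel gains,
    zero-phase Butterworth band-pass/band-stop filtering with Hilbert
    envelope extraction and resampling, trial-stratified window sampling
    with train-only z-scoring, a residual one-dimensional convolutional
    network classifier trained with Adam under stratified five-fold
    cross-validation, integrated-gradients channel attribution, and the
    accompanying statistics: permutation-based empirical chance levels with
    Cohen's d, the 5x2-CV F-test, the McNemar test with Cohen's g,
    percentage agreement and Cohen's kappa between modality models.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
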