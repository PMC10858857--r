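Package: mfccsleep
Title: Sleep Stage Classification from Polysomnography Using MFCC Features and a CNN-LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic five-class (W, S1, S2, S3, REM) sleep staging from
    multi-channel polysomnography. Reads EDF signals and plain-text or CSV
    hypnograms, extracts Mel-frequency cepstral coefficients (pre-emphasis,
    framing, Hamming window, FFT power spectrum, triangular Mel filter bank,
    DCT cepstrum) from EEG and EMG channels, composes a two-dimensional
    multi-channel three-epoch feature stream, and classifies it with a small
    convolutional network followed by a peephole LSTM layer. Includes the full
    evaluation suite (confusion matrix, accuracy, precision, recall, F1,
    Cohen's kappa, and a cubed-error Test Cost Index), a synthetic PSG
    generator with stage-dependent spectra for end-to-end testing, and a
    window/stride parameter sweep utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
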