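Package: deglutio
Title: Multimodal Swallowing-Signal Simulation, Preprocessing and
    CNN-BiLSTM Classification
Version: 0.1.0
Authors@R: person("Deglutio", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for automated swallowing-status assessment from
    dual-channel surface electromyography (digastric and sternohyoid
    muscles) and a neck-microphone acoustic channel.  Includes a
    physiology-grounded synthetic signal simulator (sequential muscle
    bursts synchronised with the three swallowing sound waves, plus
    silent-aspiration desynchronisation, cough and chewing signatures),
    zero-phase Butterworth/notch filtering, spectral-subtraction noise
    reduction, polyphase-free Fourier resampling, short-time Fourier
    spectrograms, SNR-based electrode-placement quality control,
    epoch segmentation with time-shift augmentation, participant-disjoint
    dataset splitting, a from-scratch 1-D CNN + bidirectional LSTM
    classifier trained with Adam, and per-class sensitivity/specificity
    evaluation with automatic session reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
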