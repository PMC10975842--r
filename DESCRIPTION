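Package: ecgsonify
Title: Frequency-Modulation Sonification of Multi-Lead ECG and CNN-Based
    Demodulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transmitting a diagnostic 12-lead electrocardiogram as
    a single low-band audio stream and recovering it with diagnostic fidelity.
    The eight independent ECG leads (I, II, V1-V6) are frequency-modulated onto
    carriers spaced 300 Hz apart (450-2550 Hz) and summed into one 11 kHz mono
    audio signal. Two inverse transforms are provided: a classical DSP
    demodulator (band isolation, analytic-signal instantaneous frequency) used
    as a training-free oracle, and a small four-layer 1D convolutional neural
    network (linear activations, max pooling, 23,600 parameters) trained by
    unsupervised regression to map 10 s of audio at 11 kHz back to 8-lead ECG
    at 250 Hz. Includes a synthetic multi-lead PQRST generator with fiducial
    ground truth, monitoring-band preprocessing (0.64-30 Hz first-order
    Butterworth), WFDB/CSV/WAV input-output, and the evaluation suite used to
    judge reconstruction quality: RMSE, percentage root-mean-square difference
    (PRD), fiducial-point matching with +/-50 ms tolerance (MAD, Se, PPV),
    normalized Welch power-spectral-density error, and STFT monitoring of the
    audio band structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
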