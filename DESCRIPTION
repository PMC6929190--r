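Package: heartcs
Title: Compressed Sensing Reconstruction and Biometric Identification for Cardiac Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for compressed-sensing acquisition and reconstruction of
    single-channel cardiac biosignals (ECG and PPG), and for biometric
    identification from the reconstructed signals. Provides synthetic ECG/PPG
    generators with analytic fiducial ground truth, orthonormal DCT and
    K-SVD-trained redundant sparse dictionaries, Gaussian measurement
    ensembles, greedy sparse recovery by orthogonal matching pursuit (OMP),
    stagewise weak OMP (SWOMP) and a sparsity-adaptive staged variant (SWAMP)
    with RIP-based initial sparsity estimation, reconstruction quality
    metrics (SNR, matching rate, RMSE), coif3 wavelet denoising,
    wavelet-based fiducial point detection with distance and amplitude
    feature extraction, and a one-vs-one RBF support vector machine
    identification stage with majority voting.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
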