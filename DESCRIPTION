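Package: ramanclean
Title: Self-Supervised Raman Spectral Preprocessing, Denoising and Baseline Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-supervised scheme for preprocessing Raman and SERS spectra:
    a training-data factory that decomposes measured spectra into noise,
    baseline and Raman-peak fragments by a periodized Daubechies-8 wavelet
    transform and a differential peak finder, recombines them into labelled
    reference/ideal spectrum pairs with controlled signal-to-noise ratio and
    baseline severity, optionally refines them with a conditional generative
    adversarial network, and trains a two-branch 1D convolutional
    encoder-decoder (background-estimation branch plus sliding-window patches
    branch, Inception-style down/up-sampling, two-step Huber-loss training) for
    joint denoising and baseline correction of arbitrary spectra. Includes the
    classical iterative-polynomial and wavelet-band baseline-correction methods
    for comparison, a full evaluation metric suite (RMSE, infinity norm, AUC,
    sensitivity/specificity/PPV/NPV, quantification error, spectral SNR,
    image CNR/STDB, rank tests), hyperspectral-cube utilities (per-pixel
    preprocessing, chemical channel maps, PCA feature maps) and a reproducible
    preprocessing-comparison trial workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
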