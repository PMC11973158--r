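Package: fourierpd
Title: Complex-Valued Unrolled Primal-Dual Reconstruction for Undersampled MR Thermometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to accelerate proton-resonance-frequency (PRF) shift MR
    thermometry by reconstructing retrospectively undersampled complex-valued
    gradient-echo images with unrolled primal-dual networks built from
    complex-valued convolutions (Fourier-PDNet and Fourier-PDUNet), followed by
    a k-space data-consistency step. Includes variable-density Cartesian
    sampling-mask generation (1D and 2D), centred orthonormal Fourier
    transforms, a synthetic heating-phantom generator with PRF-encoded
    hotspots, PRF-shift temperature mapping with a wrap-robust complex phase
    difference, the temperature-error statistic, and image-quality metrics
    (SSIM, NRMSE, UIQI) for magnitude and phase images. Training (complex L1
    loss, Adam with a stepped learning-rate schedule) and inference run on the
    CPU with hand-written gradients; a command-line interface covers the whole
    simulate-undersample-train-reconstruct-thermometry pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
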