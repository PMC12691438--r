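Package: zsrecon
Title: Scan-Specific Self-Supervised Accelerated MRI Reconstruction with
    Log-Scaled k-Space Losses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete pipeline for scan-specific self-supervised
    reconstruction of undersampled multicoil MRI: simulated multicoil
    acquisition with smooth complex coil sensitivities, 1D-uniform and
    2D-CAIPI sampling masks with partial Fourier, self-supervised k-space
    partitioning into input/loss/validation subsets, an unrolled dual-domain
    model-based network with conjugate-gradient data consistency and
    virtual-coil conjugate-symmetry augmentation, logarithmically scaled
    normalized l1/l2 k-space training losses, and frequency-sensitive image
    quality metrics (NRMSE, PSNR, SSIM, HFEN, GMSD). The network layers and
    their gradients are implemented natively so training runs on a plain CPU
    without external deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
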