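Package: spectraln2i
Title: Self-Supervised Denoising for Spectral Photon-Counting CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and self-supervised denoising of spectral (photon-counting)
    computed tomography data. Builds poly-energetic X-ray tube spectra, energy-resolved
    material phantoms with K-edge aware attenuation lookups, fan-beam Beer-Lambert
    projection with Poisson counting noise, channel-wise filtered backprojection with
    selectable filters, and a Noise2Inverse denoiser that trains a small U-Net on
    energy-spatial blocks extracted from leave-one-out averages of angular-subset
    reconstructions. Includes Low2High filter-pair self-supervision and total-variation
    regularised iterative reconstruction (FISTA) as baselines, and channel-wise image
    quality metrics (PSNR, MSE, SSIM, CNR, ROI attenuation profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
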