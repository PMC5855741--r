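Package: focidyn
Title: Live-Cell DNA-Damage Focus Dynamics from Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the spatiotemporal dynamics of DNA double-strand-break
    repair foci (such as 53BP1-GFP foci) in registered time-lapse images of
    single nuclei. Provides a seeded synthetic time-lapse generator with
    ground truth, rigid-body (translation + rotation) stack registration,
    focus segmentation and per-focus measurement, nearest-neighbour track
    linking with merge/split event classification, pooled mean-square
    displacement analysis with a confined-diffusion (random walk in a
    confined space) model fit, and derived kinetics statistics: smoothed
    foci-per-cell curves, summary ratios, additive mixed-beam expectations,
    fading-corrected relative intensities, coefficients of variation, and
    Gaussian kernel density estimates of focus intensity distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
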