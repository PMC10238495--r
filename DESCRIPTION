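Package: ridgemetrics
Title: Segmentation, Tracking and Biophysical Quantification of Epithelial Microridge Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to segment, track and biophysically characterize actin
    microridge patterns on the apical surface of squamous epithelial
    (periderm) cells from 4D fluorescence stacks. Provides entropy-based
    z-slice filtering and projection, Butterworth high-pass membrane
    segmentation with single-cell extraction, nearest-neighbour cell
    tracking, a rectified-Laplacian ridge labeling algorithm, a small
    U-net trainer for semantic ridge segmentation, worm-like-chain
    persistence-length and flexural-rigidity estimation from rescaled
    curvature distributions, Fourier pattern-wavelength and skeleton
    branch-length morphometrics, Lucas-Kanade optic-flow strain-rate
    analysis with area-deviatoric decomposition, and actin-cluster
    intensity-profile and Gaussian-curvature dynamics. Includes synthetic
    generators (worm-like chains, labyrinthine patterns, analytic flow
    scenes, two-layer z-stacks) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    pracma,
    graphics,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
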