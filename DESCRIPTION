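Package: beadpull
Title: Quantitative Image Analysis for Bead-Based Fluorescent Pull-Down Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification pipeline for imaging-based bead
    pull-down assays, in which GST-bait proteins immobilized on glutathione
    agarose beads retain GFP-fused prey from cell lysate and the retained
    fluorescence is read out under a microscope. Provides denoising and
    rolling-ball background subtraction, Otsu thresholding, watershed
    separation of touching beads, particle filtering by size, circularity
    and edge contact, per-bead intensity measurement with blank-bead and
    mock-lysate autofluorescence correction, exposure-time normalization,
    and the normalized bead-retained-prey affinity statistic with Welch
    t-tests and linear input-output fits. Includes a synthetic micrograph
    generator with exact ground truth so the whole pipeline is testable
    without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
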