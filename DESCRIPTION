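Package: isletmap
Title: Functional Mapping of Pancreatic Islet Calcium Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for functional mapping of pancreatic islets from
    time-lapse calcium imaging and immunofluorescence. Implements trace
    normalization (F/F_min and ratiometric modes), empirical mode
    decomposition denoising and detrending, activity binarization,
    pairwise co-activity with permutation significance, hub-cell network
    classification with connectivity maps, bias-corrected continuous
    Morlet wavelet spectra, and per-cell stain intensity quantification
    with LOW/HIGH maturity classification. A seeded synthetic-islet
    generator with planted network structure supports end-to-end testing
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
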