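Package: volraman
Title: Quantitative Volumetric Raman Imaging by Spectral Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for quantitative volumetric confocal Raman
    imaging of cells and 3D cultures. Assembles z-stacks of hyperspectral Raman
    images into a volumetric dataset, preprocesses every spectrum (PCA-based
    cosmic-ray detection and repair, iteratively reweighted polynomial baseline
    correction, Savitzky-Golay smoothing), extracts pure-component endmember
    spectra by vertex component analysis, maps per-voxel abundances by
    non-negative least squares, refolds abundances into per-component 3D
    volumes, and quantifies each component as a thresholded voxel-count
    percentage with group statistics. Includes a synthetic cell-phantom
    generator with ground truth for validation, a non-confocal z-collapse
    control, and text/TIFF import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    signal,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
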