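Package: hepavasc
Title: Multiscale Reconstruction and Morphometry of Hepatic Vasculature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs hepatic vessels from dual-channel 3D fluorescence
    volumes: denoising, gamma correction and bicubic resampling; a chunked
    multiresolution pyramid with block extraction; parameter-corrected Otsu
    segmentation with morphological cleanup (dark-lumen mode for large veins
    on the cytoarchitecture channel, bright-tube mode for sinusoids on the
    vessel channel); topology-preserving centerline skeletonization into a
    spatial graph; rayburst-style local diameter estimation; portal/hepatic
    vein classification by the accompaniment principle; and sinusoid diameter
    statistics with a 15 micrometre cutoff. Includes a synthetic dual-channel
    liver-vasculature phantom generator with exact ground truth (centerlines,
    radii, vessel classes) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
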