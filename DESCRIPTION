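Package: tessella
Title: Segmentation of Tessellated Layers in Volumetric Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A five-stage pipeline for segmenting individual tiles
    (tesserae) in 3D gray-scale images of thin, tiled biological layers
    such as the tessellated calcified cartilage of sharks and rays.
    Stages: edge-stopping anisotropic diffusion, strip-restricted local
    thresholding, a locally-planar two-dimensional distance transform
    (with the standard 3D transform as baseline), a hierarchical
    watershed with persistence- and size-based merging, and graph-based
    proofreading (merge, watershed split, spectral split). Includes a
    synthetic tessellated-shell phantom generator with ground truth,
    landmark precision/recall evaluation, Rand index and variation of
    information, and NRRD/MHD/TIFF volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    tiff
LinkingTo: Rcpp
Suggests:
    withr,
    yaml,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
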