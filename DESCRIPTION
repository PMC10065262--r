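Package: spheroidsim
Title: Synthesis and Quality Evaluation of 3D Microscopy Images of Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for generating large 3D fluorescence microscopy
    volumes of 3D cell cultures (spheroids) with voxel-accurate ground-truth
    labels. Nucleus prototypes extracted from labeled volumes are augmented,
    collision-free placed inside a generated culture shape mask, and passed
    through a confocal imaging model: occlusion-dependent brightness
    attenuation, point-spread-function convolution, anti-aliased downsampling
    and Poisson noise. Includes seam-free patch splitting for pluggable
    volume-to-volume transforms, region-split normalized Wasserstein and
    q95 edge-quality depth profiles for comparing synthetic against real
    recordings, an exact paired Wilcoxon signed-rank test, and detection
    scoring of label volumes against center-point annotations (AOGM/DET).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
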