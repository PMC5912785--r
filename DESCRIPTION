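Package: wgquant
Title: Quantitative Image Analysis of Wnt/Wingless Signaling in Segmented Embryos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying Wnt/Wingless (Wg) pathway readouts in
    multi-channel confocal stacks of segmented Drosophila embryos:
    membrane-mask-subtracted Armadillo/beta-catenin quantification across Wg
    stripes and interstripes, separation of junctional versus
    cytoplasmic/nuclear Arm pools, counting of GFP molecules in destruction
    complex puncta by dual-standard fluorescence calibration against yeast
    kinetochore clusters, percentile-threshold brightness ranking of
    subcellular structures, Engrailed row counting, and fold-ratio chaining of
    immunoblot and FPKM abundance measurements. A synthetic-image generator
    with full ground truth emulates the statistical structure of the embryo
    data so every stage of the pipeline can be verified without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization
RoxygenNote: 7.3.3
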