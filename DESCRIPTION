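Package: rootct
Title: Segmentation and Diameter Analysis of Root Systems in X-ray CT
    Volumes of Undisturbed Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting plant root systems from X-ray computed
    tomography reconstructions of soil columns, including undisturbed field
    samples containing unconnected roots of multiple plants. Implements a
    five-step segmentation protocol (gradient-refined surface determination
    of the mineral phase, fractional-voxel dilation to absorb partial-volume
    mixed voxels, domain subtraction, root surface determination, and
    connected-component size filtering), local-thickness root diameter
    distributions, an adaptive region-growing baseline, TIFF stack input and
    output with physical voxel metadata, and a synthetic soil-phantom
    generator with voxel-accurate ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
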