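Package: granulemetrics
Title: Morphometry and Quantification of Bacterial Storage Granules from
    Segmented Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of polyhydroxybutyrate (PHB) and
    polyphosphate (PP) storage granules in bacterial cells from labeled
    3D segmentation volumes. Reads MRC label volumes with voxel-size
    metadata, extracts individual granules by 3D connected-component
    labeling, and measures per-granule volume, surface area, equivalent
    spherical diameter and centroid, plus per-cell aggregates (cell
    length, granule counts, class totals). Converts PHB volume to mass
    via polymer density, computes surface-to-surface nearest-neighbor
    distances and co-localization fractions between granule classes,
    quantifies PHB from LC-MS peak-area tables via an internal-standard
    normalized calibration curve, and builds demographs of fluorescent
    foci along normalized cell length. A synthetic phantom generator
    (capsule-shaped cells, rasterized spherical granules with known
    ground truth, simulated LC-MS runs and fluorescence images) makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
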