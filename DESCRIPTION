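Package: stainsight
Title: Colorimetric Quantification of Simple-Stained Cells in Bright-Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify simple (basic-dye) staining of magnetically
    captured cells imaged on-chip with bright-field microscopes or phone
    cameras. Provides a seedable synthetic bright-field image generator with
    exact ground truth, background estimation and dark-object segmentation,
    per-band difference-from-background statistics with threshold
    classification of stains (trypan blue, safranin, methylene blue, crystal
    violet) versus beads and unstained cells, area-ratio cell counting with
    density classes, and first-to-last compartment transport-efficiency
    reports. Includes a scriptable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
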