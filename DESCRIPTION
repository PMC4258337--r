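Package: tongueseg
Title: Tongue Image Extraction in the HSI Color Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the tongue body region from color tongue
    photographs for quantitative tongue diagnosis. Implements three
    extraction pipelines in the hue-saturation-intensity (HSI) color
    space: hue binarization with morphological cleanup, hue and intensity
    thresholding with sequential connected-region labeling, and a seeded
    multiobjective greedy region-growing method that fuses color and
    spatial information so that thickly coated tongues (white or yellow
    coating) are extracted together with the tongue substance. Includes
    pixel-level accuracy metrics (recognition and error rates against
    reference masks), a synthetic tongue-scene generator with exact
    ground truth for the seven classical tongue color classes, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jpeg,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
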