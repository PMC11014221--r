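Package: roughedge
Title: Rough-Set Edge Detection for Orchard Fruit Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects fruit contours in orchard photographs by refining each
    detected fruit region (CIELAB colour conversion, K-means segmentation,
    binary morphological cleanup) and extracting its edge as the boundary
    region of a rough set: the difference between the upper and lower
    approximations of the fruit mask under a structural operator. Per-fruit
    edge maps are consolidated into a full-frame edge image. Includes a
    deterministic synthetic-orchard generator with exact ground truth
    (specular highlights, cluttered branch and leaf backgrounds, dense
    mutually occluding fruits), a windowed confusion-matrix evaluation
    protocol (precision, recall, Dice, Jaccard, area relative error, mask
    average precision), and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
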