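Package: gastrograph
Title: Graph-Based Lesion Retargeting in Endoscopic Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive multitarget tracking for gastroscopic image
    sequences. Pre-observed frames become nodes of an image graph whose
    edges carry affine transforms between highly similar frames; the
    deformation between any reference and moving frame is then solved as a
    shortest-path search over the graph, composing local affine transforms
    to retarget endoscopist-marked regions. Includes a scale-restricted
    SIFT-style feature extractor with clamp-normalized 32-dimensional
    descriptors, RANSAC affine estimation, normalized cross-correlation
    validation, Dijkstra pathway search, a forward-backward /
    Kullback-Leibler evaluation framework, and a seeded synthetic-sequence
    generator with ground-truth transforms for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
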