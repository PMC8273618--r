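Package: ccmorph
Title: Calcified Cartilage Segmentation and Thickness Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation of the calcified cartilage (CC) layer from
    histology-like 2D images and micro-CT-like 3D image stacks, and
    quantification of its thickness (CC.Th). Provides a synthetic osteochondral
    phantom generator with analytic ground truth, a compact encoder-decoder
    convolutional network trained with a combined binary cross-entropy and
    soft-Jaccard loss under subject-grouped cross-validation, tiled
    sliding-window ensemble inference with overlap and orthogonal-plane
    averaging, mask post-processing (small-region removal, largest-object
    sweep, binary median filtering), Hildebrand-Ruegsegger local thickness by
    discrete circle/sphere fitting with an exact brute-force oracle, and
    method-agreement statistics (Dice, Pearson, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
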