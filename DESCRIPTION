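Package: ttcseg
Title: Brain Slice Extraction and Hemisphere Segmentation in TTC-Stained Rat Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automatic segmentation toolkit for camera-based photographs of
    2,3,5-triphenyltetrazolium chloride (TTC) stained rat brain slices from
    experimental stroke models. Extracts individual brain slices from raw
    compound photographs via SLIC superpixel oversegmentation, per-superpixel
    colour saliency features, a random-forest saliency trimap, iterative
    GrabCut-style salient region refinement, morphological hole filling and a
    parametric active contour (snake) on a red-dominance colour transform.
    Splits each extracted slice into cerebral hemispheres with a gradient
    vector flow (GVF) guided open-curve midline. Includes a synthetic phantom
    generator with exact ground truth, a full segmentation evaluation metric
    suite (conformity, Jaccard, Dice, sensitivity, sensibility and pixel-count
    error measures) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    randomForest,
    png,
    yaml,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
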