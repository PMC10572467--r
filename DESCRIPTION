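Package: exemplarMRI
Title: Exemplar Patch Deep-Feature Pipeline for MRI Slice Classification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a patch-based ("exemplar") feature-extraction and
    classification pipeline for 2-D brain MRI slices, aimed at separating
    multiple-sclerosis from healthy-control images. Slices are cropped to the
    brain area, canonicalized to 224x224, tiled into non-overlapping 28x28
    exemplar patches, and passed through a pluggable feature backbone (a
    deterministic mock projection or a small trainable CNN) yielding 1000
    features per patch and per whole image, merged into a 65,000-dimensional
    vector. Features are ranked by greedy minimum-redundancy
    maximum-relevance (mRMR) mutual information and the subset size is chosen
    by cross-validated misclassification; classification uses a
    random-subspace k-nearest-neighbour ensemble (30 learners, subspace
    dimension 86) under stratified 10-fold cross-validation with per-class
    one-vs-rest metrics. A synthetic lesion-image generator provides
    download-free test data with pixel-level ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class,
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Preprocessing
RoxygenNote: 7.3.3
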