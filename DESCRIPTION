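Package: amyloidHOG
Title: Amyloid-Status Classification of PET Volumes with 3D Histograms of
    Oriented Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies brain amyloid status (positive/negative) from
    spatially normalized, skull-stripped amyloid PET volumes using
    tracer-independent feature vectors built from histograms of oriented 3D
    gradients (3D HOG). Mean gradients over cuboidal sub-blocks are obtained
    in constant time from per-axis integral gradient volumes, quantized onto
    the face centers of a Platonic solid (dodecahedron or icosahedron, full
    or half orientation), accumulated into per-cell histograms and classified
    with an RBF-kernel support vector machine (stratified cross-validated
    grid search, leave-one-out evaluation, ROC analysis). Two comparator
    methods are included: composite standardized uptake value ratios (SUVR)
    with cross-scale positivity-threshold conversion, and a per-image
    z-normalized voxel-intensity SVM baseline. A synthetic phantom generator
    produces PET-like volumes with known ground truth so the entire pipeline
    can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'gradient.R'
    'hog3d.R'
    'intensity.R'
    'orientation.R'
    'phantom.R'
    'regions.R'
    'suvr.R'
    'svm.R'
    'volume.R'
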