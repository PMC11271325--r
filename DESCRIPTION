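Package: octavad
Type: Package
Title: Vessel Area Density and Lesion Overlap Analysis for En-Face OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies perfusion in en-face optical coherence tomography
    angiography (OCTA) slabs around focal macular lesions. Builds intra-eye
    control regions from a human lesion segmentation (an adjacent tissue
    control obtained by scaling the lesion about its centroid, and a
    fovea-centred ring segment whose bounding circles are tangent to the
    lesion), measures vessel area density per vascular slab with Otsu
    thresholding and Frangi-based large-vessel exclusion in the superficial
    plexus, scores lesion overlap between infrared and en-face OCT
    segmentations with the Sorensen-Dice coefficient, and aggregates eyes
    with paired t-tests under Bonferroni correction. A seeded synthetic OCTA
    phantom generator lets the entire pipeline be exercised and calibrated
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    RNifti,
    EBImage,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
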