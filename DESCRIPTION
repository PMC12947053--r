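Package: sphereseg
Title: Uncertainty-Guided Hybrid Segmentation with Spherical Projection Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An uncertainty-guided coarse-to-fine framework for volumetric
    segmentation of multi-parametric MRI. A spherical-projection test-time
    ensemble turns any 2D slice segmenter into a voxel-wise Shannon-entropy
    uncertainty map; a summed-area-table sliding-window search with greedy
    overlap-constrained selection localizes high-uncertainty cubic subvolumes;
    a local 3D segmenter refines them; and a particle-swarm-optimized
    sigmoid rule fuses the global 2D and composite 3D probabilities.
    Includes a synthetic nested-ellipsoid tumor phantom generator, NIfTI
    input/output, segmentation metrics (Dice, 95th-percentile Hausdorff
    distance, sensitivity, specificity, accuracy), and a Wilcoxon
    signed-rank comparison protocol with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
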