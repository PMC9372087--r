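Package: rtseval
Title: Geometric and Dosimetric Evaluation of Auto-Segmented Radiotherapy Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for deep-learning auto-segmented radiotherapy
    planning structures against reference manual contours. Computes geometric
    agreement metrics (Dice similarity coefficient, Jaccard coefficient, full
    and 95th-percentile Hausdorff surface distance in physical millimetres),
    recomputes dose-volume indices (D_mean, D_max, V_100, D_x%, D_0.03cc) when
    auto contours are substituted into a fixed dose distribution, and runs the
    agreement and correlation statistics used in contour-evaluation studies
    (Bland-Altman limits of agreement, Wilcoxon paired signed-rank test,
    Spearman rank correlation). Includes a synthetic pelvic-phantom cohort
    generator with nine named planning structures, a perturbation model for
    emulating auto-segmentation error, a conformal dose surrogate, and a small
    encoder-decoder convolutional network so the full segment-then-evaluate
    workflow runs end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
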