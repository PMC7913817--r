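Package: spineqct
Title: Opportunistic QCT Spine Densitometry and Abdominal Fat Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for opportunistic osteoporosis assessment in routine
    contrast-enhanced multi-detector CT: per-scan synchronous calibration of
    Hounsfield units to volumetric bone mineral density using a two-phase
    density reference phantom, standardized trabecular region-of-interest
    densitometry at every vertebral level Th5-L5, subcutaneous and visceral
    adipose tissue quantification over a five-slice window at the L4/5 disc,
    and the matched case-control statistical battery (Wilcoxon signed-rank
    comparisons, Spearman correlations, nonparametric ROC/AUC with
    Hanley-McNeil standard errors, odds ratios per SD decrease, forward
    stepwise logistic regression). A synthetic-CT and synthetic-cohort
    generator with voxel-level ground truth makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
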