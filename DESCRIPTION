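Package: boldln
Title: Renal BOLD-MRI R2* Analysis and Histopathological Class Prediction in Lupus Nephritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise R2* relaxometry from multi-echo BOLD magnetic resonance
    images of the kidney, random sampling of consecutive-voxel groups from
    regions of interest, a ten-statistic feature set per group, three
    group-level classifiers (Fisher linear discriminant, binary logistic
    regression, and a CHAID decision tree grown from scratch), majority-vote
    aggregation of group predictions to patient-level histopathological class
    (ISN/RPS III vs IV, pure vs superimposed membranous), and diagnostic-test
    evaluation (sensitivity, specificity, accuracy, Youden index, AUROC with
    paired DeLong comparison, leave-one-out cross-validation). Includes a
    synthetic-cohort generator with cortex/medulla contrast and
    gamma-distributed medullary R2*, and machine-readable transcriptions of a
    published twelve-patient study's clinical, pathology and vote tables from
    which every printed evaluation metric is recomputable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
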