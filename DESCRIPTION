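Package: cavquant
Title: Quantification of Gray Matter Displaced by Cerebral Cavernous
    Malformations and Associated Seizure-Risk Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise quantification of the gray matter (GM) displaced by
    a cerebral cavernous malformation (CCM), using a population GM density
    template as reference. Builds density templates by voxel-wise averaging
    of control GM maps, computes the displaced-GM volume (thresholded voxel
    count) and proportion (mean in-lesion density) from co-registered NIfTI-1
    lesion labels, attributes lesions to eight merged anatomical lobes via a
    parcellation atlas, and reproduces cohort-level seizure-risk statistics:
    odds ratios with Woolf confidence intervals, Fisher and Wilcoxon tests,
    logistic regression with Hosmer-Lemeshow goodness of fit and calibration
    slope, threshold-classifier metrics (sensitivity, specificity, PPV, NPV,
    F1, DOR, MCC, kappa) with stratified bootstrap intervals, ROC/AUC with
    Youden threshold selection, and the Bayesian prevalence-adjusted
    predicted PPV. A seeded synthetic-cohort generator produces density
    templates, lesion masks with known ground truth, a lobe parcellation,
    and outcome labels drawn from a stated logistic model, so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
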