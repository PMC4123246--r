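Package: smvdiscover
Title: Quality-Aware Serum Proteomic Biomarker Discovery and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A workflow for discovering and validating case/control serum
    protein biomarkers from affinity-proteomic (RFU) matrices in the presence
    of preanalytic confounding. Implements Sample Mapping Vector (SMV) panel
    scoring to flag blood samples affected by cell lysis, complement
    activation or platelet activation; quality-stratified candidate selection
    by two-sample Kolmogorov-Smirnov tests with Benjamini-Hochberg control;
    robustness filtering against contamination scores and cross-site
    inconsistency; backward elimination of a bagged decision-tree classifier
    by gini importance with out-of-bag AUC; and prevalence-adjusted
    diagnostic performance reporting (ROC/AUC, Wilson intervals, Bayes
    PPV/NPV). Includes a multi-site synthetic cohort generator with planted
    disease markers and planted collection-quality confounding for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
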