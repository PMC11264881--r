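Package: neometab
Title: Neonatal Dried-Blood-Spot Metabolome-Wide Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for metabolome-wide case-control analysis of untargeted
    LC-MS feature tables from neonatal dried blood spots: QC-based LOESS
    injection-order drift correction and plate batch correction,
    missingness-stratified feature handling (drop / binary / continuous),
    covariate-adjusted logistic association with false-discovery-rate
    control, metabolite-class enrichment, partial-correlation networks,
    MS/MS cosine spectral library matching, an additive per-SNP scan and
    LASSO determinant scan for metabolite levels, and a synthetic cohort
    generator with planted effects for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    rpart,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
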