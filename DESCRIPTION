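Package: metabostab
Title: Stability-Validated All-Relevant Metabolite Selection for
    Targeted Metabolomics Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted metabolomics concentration
    panels (Biocrates p180-style) used to discriminate animal groups such
    as pig breeds. Provides quality-control filtering (replicate CV, limit
    of detection, missing/zero rates, outlier screening), covariate
    residualization on sex and carcass weight, an all-relevant feature
    selection core (shadow-feature random-forest wrapper with binomial hit
    testing) validated by a multi-seed leave-one-out stability scheme with
    reliability classification, downstream evaluation (relative
    concentration differences, Gini importance, out-of-bag error, ROC-AUC,
    Mann-Whitney U tests with Bonferroni correction, within-group
    correlation screens), principal component analysis, and a synthetic
    panel generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
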