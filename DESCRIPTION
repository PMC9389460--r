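Package: colpocad
Title: Multimodal Computer-Aided Diagnosis of Cervical Dysplasia from
    Colposcopic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage computer-aided diagnosis pipeline for cervical
    dysplasia screening from paired colposcopic images (visual inspection
    with acetic acid, VIA, and with Lugol's iodine, VILI) and clinical
    covariates (age, HPV genotyping, cervical cytology). The pipeline crops
    images to an annotated or automatically detected cervix region, extracts
    65 colour-channel statistics and 24 gray-level co-occurrence (Haralick)
    texture features per image, ranks features by Welch t-tests with
    Benjamini-Hochberg adjustment, rebalances the skewed high-grade versus
    low-grade/normal classes with SMOTE, classifies with a radial-basis
    support vector machine, and fuses the resulting class probability with
    clinical covariates in a mixed-family naive Bayes stage. Evaluation
    utilities provide sensitivity, specificity, accuracy, a macro-averaged
    F1 built from per-class sensitivity and specificity, the area under the
    precision-recall curve, and the model-or-physician combination rule. A
    seeded synthetic cervigram generator makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
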