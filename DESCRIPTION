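Package: fundusshift
Title: Distribution Shift Detection for Image-Based Model Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects distribution shifts between a validation (source) and a
    deployment (target) sample of medical images using three two-sample
    hypothesis tests built on learned image representations: a classifier
    two-sample test (C2ST), a trainable deep-kernel maximum mean discrepancy
    test (MMDD), and multiple univariate Kolmogorov-Smirnov tests on the
    softmax outputs of the monitored task model (MUKS). Includes a synthetic
    fundus-image generator with controllable subgroup structure (patient sex,
    ethnicity, image quality, co-morbidities, diabetic retinopathy grade), a
    declarative shift simulator (subgroup filtering, oversampling,
    out-of-distribution quality shifts), and a power / type-I-error
    evaluation harness for benchmarking the detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    glmnet,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
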