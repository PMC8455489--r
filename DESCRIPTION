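Package: scdecode
Title: Brain Decoding of Real-Life Self-Control from Preference Decision fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking laboratory preference decisions to
    real-life self-control. Summarises ecological momentary assessment (EMA)
    records into per-subject self-control-failure probabilities, classifies
    trials by the sign structure of rated short- and long-term consequences,
    fits first-level fMRI general linear models with a canonical
    haemodynamic response and cosine high-pass drift, performs second-level
    one-sample t inference with random-field-theory family-wise error
    correction and cluster-extent thresholding to define parietal regions of
    interest, and predicts each subject's failure probability from ROI
    activity patterns with L1-regularised logistic regression under nested
    leave-one-subject-out cross-validation and permutation inference. A
    synthetic-data module generates complete multi-subject datasets (EMA,
    behaviour, BOLD, ground truth) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    glmnet,
    RNifti,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    knitr
Config/testthat/edition: 3
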