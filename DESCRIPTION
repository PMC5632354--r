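Package: adhdml
Title: Multi-Domain Machine-Learning Classification of ADHD from
    Neuropsychological, Blood Fatty-Acid and fNIRS Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating a multi-domain diagnostic
    classifier for attention deficit/hyperactivity disorder (ADHD) versus
    typically developing (TD) children. Implements block-design functional
    near-infrared spectroscopy (fNIRS) preprocessing (zero-phase low-pass
    filtering, stimulus-aligned epoching, short-baseline z-scoring,
    condition and grand averaging), PCA feature extraction with Fisher
    discriminant ratio ranking and top-fraction retention, exhaustive
    wrapper feature-subset optimisation with linear support vector machines
    inside a nested 10-fold cross-validation, occurrence-frequency feature
    importance, and majority-vote ensembling of domain-specific predictive
    models. A synthetic multi-domain cohort generator with a configurable
    N-back block protocol makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
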