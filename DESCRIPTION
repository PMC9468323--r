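Package: dfclstm
Title: Dynamic Functional Connectivity of rs-fMRI with Group ICA and
    LSTM Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying brain disorders from resting-state
    fMRI via dynamic functional connectivity among independent
    components.  Implements group spatial ICA (two-stage PCA reduction,
    Infomax unmixing, ICASSO-style stability assessment, dual-regression
    back-reconstruction), sliding-window Pearson correlation networks at
    the component and atlas-ROI level, a long short-term memory (LSTM)
    sequence classifier with SVM and random-forest baselines on static
    connectivity, a stratified cross-validation harness with
    confusion-matrix metrics (accuracy, sensitivity, specificity, F1,
    Cohen's kappa, Jaccard, AUC), and a synthetic cohort generator with
    state-switching inter-component covariance and planted group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    signal,
    e1071,
    randomForest,
    yaml,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
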