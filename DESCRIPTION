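Package: impactkit
Title: Head-Impact Detection from Instrumented-Mouthguard Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying threshold-triggered captures from an
    instrumented mouthguard into head impacts ("hits") and non-impact
    artifacts (chewing, yelling, mouthguard handling). Implements the full
    pipeline: a synthetic capture simulator with realistic sensor models
    (triaxial accelerometers at 3,200 Hz, gyroscope at 800 Hz, quantization,
    rate jitter), onboard 10 g trigger emulation, 300 Hz Butterworth triage
    filtering, polyphase resampling and axis alignment, random convolutional
    kernel and binned Welch power-spectral-density features, class balancing
    and stratified splitting, baseline classifier sweeps, MCC-optimized
    randomized hyperparameter search for gradient-boosted trees, bootstrap
    confidence intervals for classification metrics, and tree-SHAP based
    feature attribution summaries.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    ranger,
    rpart,
    MASS,
    glmnet,
    class
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
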