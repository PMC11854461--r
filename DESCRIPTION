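Package: adspectrum
Title: Staging the Alzheimer's Disease Spectrum from Task-Based EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying the Alzheimer's disease spectrum
    (subjective cognitive decline, mild cognitive impairment, Alzheimer's
    dementia) from short task-based and resting-state EEG. Provides a
    synthetic cohort generator with group-conditional spectral slowing and
    behavioral profiles, a minimal EEG preprocessing chain (downsampling,
    band-pass and notch filtering, average referencing, ICA-based artifact
    removal, epoching), an attention-weighted LSTM and a
    convolution-transformer sequence classifier implemented natively,
    a PCA+SVM shallow baseline, subject-wise cross-validated training with
    class weighting and early stopping, trial- and participant-level
    evaluation (confusion matrices, weighted metrics, one-vs-rest AUC,
    majority voting), and nonparametric behavioral group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, signal, e1071, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
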