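Package: eegaug
Title: Generative and Synthetic Augmentation for Imbalanced EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying class-imbalance remedies in
    EEG seizure detection. Simulates patient-structured multichannel EEG with
    rare rhythmic seizure epochs, extracts a 44-feature-per-channel time and
    frequency descriptor set (band powers, moments, empirical mode
    decomposition, sample and permutation entropies, Hjorth parameters,
    wavelet and wavelet-packet entropies and energies, successive
    decomposition index), balances the minority class with SMOTE, ADASYN,
    class weighting or generative adversarial networks (vanilla, conditional,
    Cramer-surrogate and Wasserstein with gradient penalty), quantifies
    synthetic-data fidelity (quantile-quantile pairing, 2-D projections,
    energy distance), and evaluates Random Forest and LSTM classifiers under
    patient-grouped 10-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    kernlab,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), pracma, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
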