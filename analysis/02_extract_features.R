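#!/usr/bin/env Rscript
# Step 2 — per-epoch feature extraction.
#
# Reads the EDF dataset written by step 1 and computes the 44-per-channel
# descriptor set (836 features for the 19-channel montage): band powers,
# moments, first-IMF statistics, sample/permutation entropies, Hjorth
# parameters, spectral entropy, wavelet and wavelet-packet features, SDI
# and energies. Writes results/features.csv plus the feature dictionary.

library(eegaug)

tab <- run_extract("results/data", "results/features.csv")
cat(sprintf("extracted %d epochs x %d features (%.1f%% positive)\n",
            nrow(tab), length(feature_columns(tab)), 100 * mean(tab$label)))
cat("feature table -> results/features.csv\n")
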